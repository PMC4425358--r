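"""Online l1 dictionary-learning baseline: fit atoms with mini-batch
dictionary learning, encode every patch with lasso coordinate descent.

Usage: python linsc_baseline.py WORKDIR a H n_train max_iter seed
Reads WORKDIR/Y.csv (one patch per row), writes dict.csv (H x D, rows are
unit-norm atoms) and codes.csv (N x H).
"""
import sys

import numpy as np
from sklearn.decomposition import MiniBatchDictionaryLearning, sparse_encode

def main():
    wd, a, H, n_train, max_iter, seed = sys.argv[1:7]
    a, H, n_train, max_iter, seed = (float(a), int(H), int(n_train),
                                     int(max_iter), int(seed))
    Y = np.loadtxt(f"{wd}/Y.csv", delimiter=",", ndmin=2)
    rng = np.random.RandomState(seed)
    train = Y
    if Y.shape[0] > n_train:
        train = Y[rng.choice(Y.shape[0], n_train, replace=False)]
    dl = MiniBatchDictionaryLearning(
        n_components=H, alpha=a, max_iter=max_iter, batch_size=256,
        fit_algorithm="cd", transform_algorithm="lasso_cd",
        transform_alpha=a, positive_code=False, random_state=seed)
    dl.fit(train)
    codes = sparse_encode(Y, dl.components_, algorithm="lasso_cd",
                          alpha=a, max_iter=5000)
    np.savetxt(f"{wd}/dict.csv", dl.components_, delimiter=",")
    np.savetxt(f"{wd}/codes.csv", codes, delimiter=",")

if __name__ == "__main__":
    main()
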