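#!/usr/bin/env python
"""Independent non-negative Tucker decomposition reference.

Plain-numpy multiplicative-update NTD used as a cross-check oracle by the
R test suite: reads a JSON spec {"tensor": nested list, "ranks": [r1,r2,r3],
"iters": n, "restarts": m, "seed": s} on stdin and prints the best final
squared-Frobenius reconstruction loss as JSON. Written independently of the
R implementation (numpy unfolding conventions, single eps, plain loops).
"""
import json
import sys

import numpy as np


def unfold(T, mode):
    return np.moveaxis(T, mode, 0).reshape(T.shape[mode], -1)


def reconstruct(G, U):
    T = G
    for m, u in enumerate(U):
        T = np.moveaxis(np.tensordot(u, T, axes=(1, m)), 0, m)
    return T


def ntd_once(X, ranks, iters, rng):
    eps = 1e-12
    d = X.shape
    U = [rng.uniform(0.1, 1.0, (d[m], ranks[m])) for m in range(3)]
    G = rng.uniform(0.1, 1.0, tuple(ranks))
    for _ in range(iters):
        for m in range(3):
            others = [i for i in range(3) if i != m]
            # columns of mode-m unfolding: remaining axes in their order,
            # trailing axis fastest under numpy reshape (C order)
            W = np.kron(U[others[0]], U[others[1]])
            Gm = unfold(G, m)
            Xm = unfold(X, m)
            B = W @ Gm.T
            U[m] *= (Xm @ B) / (U[m] @ (B.T @ B) + eps)
        num = X
        for m in range(3):
            num = np.moveaxis(np.tensordot(U[m].T, num, axes=(1, m)), 0, m)
        den = G
        for m in range(3):
            UtU = U[m].T @ U[m]
            den = np.moveaxis(np.tensordot(UtU, den, axes=(1, m)), 0, m)
        G *= num / (den + eps)
    return float(np.sum((X - reconstruct(G, U)) ** 2))


def scalar(v):
    return v[0] if isinstance(v, list) else v


def main():
    spec = json.load(sys.stdin)
    X = np.asarray(spec["tensor"], dtype=float)
    ranks = [int(r) for r in spec["ranks"]]
    rng = np.random.default_rng(int(scalar(spec.get("seed", 0))))
    iters = int(scalar(spec.get("iters", 200)))
    losses = [ntd_once(X, ranks, iters, rng)
              for _ in range(int(scalar(spec.get("restarts", 3))))]
    json.dump({"loss": min(losses)}, sys.stdout)


if __name__ == "__main__":
    main()
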