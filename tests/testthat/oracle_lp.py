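#!/usr/bin/env python
"""Independent LP oracle for flux programs.

Reads a JSON list of problems on stdin, solves each with scipy's HiGHS
solver, writes a JSON list of {status, objective, V} to stdout.

Problem fields: S (row-major nested list), lb, ub, abs_w (optional,
coefficients on |V|), lin_w (optional, coefficients on V), lock_w /
lock_rhs (optional constraint sum lock_w*|V| <= lock_rhs), maximize.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve(problem):
    S = np.array(problem["S"], dtype=float)
    lb = np.array(problem["lb"], dtype=float)
    ub = np.array(problem["ub"], dtype=float)
    n = S.shape[1]
    abs_w = np.array(problem.get("abs_w") or [0.0] * n)
    lin_w = np.array(problem.get("lin_w") or [0.0] * n)
    # split V = f - r, f,r >= 0
    A_eq = np.hstack([S, -S])
    b_eq = np.zeros(S.shape[0])
    c = np.concatenate([abs_w + lin_w, abs_w - lin_w])
    if problem.get("maximize"):
        c = -c
    bounds = [(max(0.0, lb[i]), max(0.0, ub[i])) for i in range(n)] + [
        (max(0.0, -ub[i]), max(0.0, -lb[i])) for i in range(n)
    ]
    A_ub = None
    b_ub = None
    if problem.get("lock_w") is not None:
        w = np.array(problem["lock_w"], dtype=float)
        A_ub = np.concatenate([w, w])[None, :]
        b_ub = [float(problem["lock_rhs"])]
    res = linprog(c, A_ub=A_ub, b_ub=b_ub, A_eq=A_eq, b_eq=b_eq,
                  bounds=bounds, method="highs")
    if not res.success:
        return {"status": "infeasible", "objective": None, "V": None}
    V = res.x[:n] - res.x[n:]
    obj = float(abs_w @ np.abs(V) + lin_w @ V)
    return {"status": "optimal", "objective": obj, "V": V.tolist()}


def main():
    problems = json.load(sys.stdin)
    json.dump([solve(p) for p in problems], sys.stdout)


if __name__ == "__main__":
    main()
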