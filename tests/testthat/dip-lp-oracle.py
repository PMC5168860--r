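#!/usr/bin/env python
"""Independent dip oracle via linear programming (scipy HiGHS).

Solves the definitional minimisation dip = min over unimodal CDFs G of
sup |F_n - G|.  A unimodal CDF is convex left of its mode, concave right of
it, and may carry an atom only at the mode.  Mode placements are enumerated:
inside a segment between adjacent unique values (the modal chord must be at
least as steep as the flatter neighbouring slope -- a disjunction, two LP
branches) or at a knot (where G may jump: the left limit is tested against
the upper ECDF anchor, the value against the lower anchor).

Usage: python dip-lp-oracle.py < samples.tsv > dips.txt
Each input line: whitespace-separated sample values.
"""
import sys
import numpy as np
from scipy.optimize import linprog


def dip_lp(x):
    x = np.sort(np.asarray(x, dtype=float))
    n = len(x)
    u, counts = np.unique(x, return_counts=True)
    m = len(u)
    if m == 1:
        return 0.0
    F = np.cumsum(counts) / n
    A = np.concatenate(([0.0], F[:-1]))   # upper anchors
    B = F                                  # lower anchors
    du = np.diff(u)
    best = np.inf

    def solve(c, A_ub, b_ub):
        res = linprog(c, A_ub=np.array(A_ub), b_ub=np.array(b_ub),
                      bounds=[(0, None)] * len(c), method="highs")
        return res.fun if res.status == 0 else np.inf

    def norm(row):
        mx = np.max(np.abs(row))
        return [v / mx for v in row] if mx > 0 else row

    def srow(nv, j):           # slope j coefficients scaled by du_j
        r = [0.0] * nv
        r[j] = -1.0
        r[j + 1] = 1.0
        return r, du[j]

    def slope_le(nv, j1, j2):  # s_{j1} <= s_{j2}, cross-multiplied
        r1, d1 = srow(nv, j1)
        r2, d2 = srow(nv, j2)
        return [a * d2 - b * d1 for a, b in zip(r1, r2)]

    def seg(q, branch):
        nv = m + 1                         # g_1..g_m, d
        di = m
        c = [0.0] * nv
        c[di] = 1.0
        A_ub, b_ub = [], []

        def le(row, rhs):
            A_ub.append(norm(row)); b_ub.append(rhs)
        for j in range(m):
            r = [0.0] * nv; r[j] = 1.0; r[di] = -1.0; le(r, A[j])     # g_j - d <= A_j
            r = [0.0] * nv; r[j] = -1.0; r[di] = -1.0; le(r, -B[j])   # -g_j - d <= -B_j
        for j in range(m - 1):
            r = [0.0] * nv; r[j] = 1.0; r[j + 1] = -1.0; le(r, 0.0)   # monotone
        for j in range(0, q - 1):
            le(slope_le(nv, j, j + 1), 0.0)                           # convex side
        for j in range(q + 1, m - 2):
            le([-v for v in slope_le(nv, j, j + 1)], 0.0)             # concave side
        if branch == "L" and q >= 1:
            le(slope_le(nv, q - 1, q), 0.0)
        if branch == "R" and q <= m - 3:
            le([-v for v in slope_le(nv, q, q + 1)], 0.0)
        return solve(c, A_ub, b_ub)

    def atom(j):
        has_a = j > 0
        nv = m + 1 + (1 if has_a else 0)   # g_1..g_m, d, [a]
        di = m
        ai = nv - 1
        c = [0.0] * nv
        c[di] = 1.0
        A_ub, b_ub = [], []

        def le(row, rhs):
            A_ub.append(norm(row)); b_ub.append(rhs)
        for i in range(m):
            ub = B[i] if i == j else A[i]
            r = [0.0] * nv; r[i] = 1.0; r[di] = -1.0; le(r, ub)
            r = [0.0] * nv; r[i] = -1.0; r[di] = -1.0; le(r, -B[i])
        if has_a:
            r = [0.0] * nv; r[ai] = 1.0; r[di] = -1.0; le(r, A[j])
            r = [0.0] * nv; r[ai] = -1.0; r[di] = -1.0; le(r, -A[j])
            r = [0.0] * nv; r[j - 1] = 1.0; r[ai] = -1.0; le(r, 0.0)   # g_{j-1} <= a
            r = [0.0] * nv; r[ai] = 1.0; r[j] = -1.0; le(r, 0.0)       # a <= g_j
        for i in range(m - 1):
            if i == j - 1:
                continue
            r = [0.0] * nv; r[i] = 1.0; r[i + 1] = -1.0; le(r, 0.0)
        # left chain slopes: s_0 <= ... <= s_{j-3} <= s_{j-2} <= slope into a
        if has_a and j >= 2:
            ra, da = srow(nv, j - 2)
            sa = [0.0] * nv
            sa[j - 1] = -1.0
            sa[ai] = 1.0
            dsa = du[j - 1]
            le([x * dsa - y * da for x, y in zip(ra, sa)], 0.0)        # s_{j-2} <= s_a
            for i in range(0, j - 2):
                le(slope_le(nv, i, i + 1), 0.0)
        # right chain slopes: slope out of g_j >= s_{j+1} >= ...
        if j <= m - 3:
            le([-v for v in slope_le(nv, j, j + 1)], 0.0)
            for i in range(j + 1, m - 2):
                le([-v for v in slope_le(nv, i, i + 1)], 0.0)
        return solve(c, A_ub, b_ub)

    for q in range(m - 1):
        if q == 0 or q == m - 2:
            best = min(best, seg(q, "none"))
        else:
            best = min(best, seg(q, "L"), seg(q, "R"))
    for j in range(m):
        best = min(best, atom(j))
    return best


def main():
    for line in sys.stdin:
        vals = [float(v) for v in line.split()]
        if not vals:
            continue
        sys.stdout.write("%.17g\n" % dip_lp(vals))


if __name__ == "__main__":
    main()
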