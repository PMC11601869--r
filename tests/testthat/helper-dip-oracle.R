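# Definitional brute-force oracle for the Hartigan dip statistic.
#
# dip(x) = min over unimodal CDFs G of sup |F_n - G|.  Reduction to linear
# constraints at the unique order statistics t_1 < ... < t_m with cumulative
# ecdf fractions c_1 < ... < c_m:
#     G(t_j)   >= c_j     - eps      (lower band)
#     G(t_j^-) <= c_{j-1} + eps      (upper band)
# G is convex left of its mode and concave right of it (open half-lines, so
# an atom at the mode is allowed: the mode knot splits into a left limit v
# bound only by the upper band and a right value w bound by the lower band
# and the following step's upper band).  For each candidate mode knot the
# minimal eps is a linear program in the fitted values; the dip is the
# minimum over mode knots.
#
# The LPs are built and solved independently of the package implementation,
# in Python with scipy's HiGHS solver (exact simplex-based LP, part of the
# pinned test environment), batched through a single subprocess call.

dip_oracle_python <- '
import json, sys
import numpy as np
from scipy.optimize import linprog

def dip_lp(xs):
    xs = np.sort(np.asarray(xs, dtype=float))
    n = len(xs)
    t, counts = np.unique(xs, return_counts=True)
    m = len(t)
    if m == 1:
        return 0.0
    cum = np.cumsum(counts) / n          # c_j
    prev = np.concatenate([[0.0], cum[:-1]])  # c_{j-1}
    best = np.inf
    for k in range(m):                   # mode knot (0-based)
        # chain positions 0..m: position k is v, k+1 is w, others are knots
        knot = list(range(k)) + [k, k] + list(range(k + 1, m))
        tt = t[np.array(knot)]
        nv = m + 2                       # chain values + eps (last)
        A, b = [], []
        def le(coefs, rhs):              # sum coefs*x <= rhs
            row = np.zeros(nv)
            for i, c in coefs: row[i] = c
            A.append(row); b.append(rhs)
        E = m + 1                        # eps index
        for ci in range(m + 1):
            j = knot[ci]
            if ci == k:                  # v: upper band only
                le([(ci, 1.0), (E, -1.0)], prev[j])
            elif ci == k + 1:            # w: lower band + next step upper
                le([(ci, -1.0), (E, -1.0)], -cum[j])
                le([(ci, 1.0), (E, -1.0)], cum[j])
            else:
                le([(ci, 1.0), (E, -1.0)], prev[j])
                le([(ci, -1.0), (E, -1.0)], -cum[j])
        for ci in range(m):              # monotone
            le([(ci, 1.0), (ci + 1, -1.0)], 0.0)
        for ci in range(1, k):           # convex left of the mode
            d1 = tt[ci] - tt[ci - 1]; d2 = tt[ci + 1] - tt[ci]
            le([(ci + 1, -1.0 / d2), (ci, 1.0 / d2 + 1.0 / d1),
                (ci - 1, -1.0 / d1)], 0.0)
        for ci in range(k + 2, m):       # concave right of the mode
            d1 = tt[ci] - tt[ci - 1]; d2 = tt[ci + 1] - tt[ci]
            le([(ci + 1, 1.0 / d2), (ci, -1.0 / d2 - 1.0 / d1),
                (ci - 1, 1.0 / d1)], 0.0)
        obj = np.zeros(nv); obj[E] = 1.0
        bounds = [(0.0, 1.0)] * (m + 1) + [(0.0, None)]
        r = linprog(obj, A_ub=np.array(A), b_ub=np.array(b), bounds=bounds,
                    method="highs")
        if r.status != 0:
            raise RuntimeError("LP solve failed: status %d" % r.status)
        best = min(best, r.fun)
    return float(best)

samples = json.load(open(sys.argv[1]))
out = [dip_lp(s) for s in samples]
json.dump(out, open(sys.argv[2], "w"))
'

# Compute oracle dip values for a list of numeric samples (small n only).
dip_oracle <- function(samples) {
  stopifnot(is.list(samples))
  tmp <- tempfile(fileext = ".py")
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(tmp, fin, fout)), add = TRUE)
  writeLines(dip_oracle_python, tmp)
  # rescale each sample to [0, 1]: the dip is affine-invariant and this
  # conditions the LP
  samples <- lapply(samples, function(x) {
    x <- sort(x)
    (x - x[1]) / max(diff(range(x)), 1e-300)
  })
  jsonlite::write_json(samples, fin, digits = NA)
  status <- system2("python", c(tmp, fin, fout), stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    stop("dip oracle subprocess failed: ", paste(status, collapse = "\n"))
  }
  as.numeric(jsonlite::read_json(fout, simplifyVector = TRUE))
}
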