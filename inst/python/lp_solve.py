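"""Batch LP/MILP solver bridge.

Reads a JSON file with a list of problems, solves each with HiGHS via
scipy.optimize.milp, and writes a JSON file with one result per problem.

Problem schema (all vectors dense unless noted):
  nvar      : number of variables
  obj       : objective coefficients (length nvar)
  maximize  : bool
  A         : {"i": [...], "j": [...], "x": [...], "nrow": int}  1-based triplets
  row_lb, row_ub : constraint row bounds (length nrow)
  lb, ub    : variable bounds (length nvar); |value| >= 1e29 means +/-inf
  int_vars  : 1-based indices of integer (binary) variables
Result schema:
  status    : "optimal" | "infeasible" | "unbounded" | "limit" | "error"
  objective : number (present when optimal)
  x         : solution vector (present when optimal)
"""
import json
import sys

import numpy as np
from scipy.optimize import milp, LinearConstraint, Bounds
from scipy.sparse import csr_matrix

INF_SENTINEL = 1e29


def _clean(v):
    v = np.atleast_1d(np.asarray(v, dtype=float))
    v = np.where(v >= INF_SENTINEL, np.inf, v)
    v = np.where(v <= -INF_SENTINEL, -np.inf, v)
    return v


def solve_one(p):
    nvar = int(p["nvar"])
    obj = np.atleast_1d(np.asarray(p["obj"], dtype=float))
    sign = -1.0 if p.get("maximize", False) else 1.0
    lb = _clean(p["lb"])
    ub = _clean(p["ub"])
    integrality = np.zeros(nvar)
    int_vars = p.get("int_vars", []) or []
    if isinstance(int_vars, int):
        int_vars = [int_vars]
    for k in int_vars:
        integrality[int(k) - 1] = 1
    constraints = []
    a = p.get("A") or {}
    nrow = int(a.get("nrow", 0))
    if nrow > 0:
        i = np.atleast_1d(np.asarray(a.get("i", []), dtype=int)) - 1
        j = np.atleast_1d(np.asarray(a.get("j", []), dtype=int)) - 1
        x = np.atleast_1d(np.asarray(a.get("x", []), dtype=float))
        A = csr_matrix((x, (i, j)), shape=(nrow, nvar))
        constraints = [LinearConstraint(A, _clean(p["row_lb"]), _clean(p["row_ub"]))]
    opts = {"mip_rel_gap": 0.0}
    opts.update(p.get("options", {}) or {})
    res = milp(
        c=sign * obj,
        constraints=constraints,
        bounds=Bounds(lb, ub),
        integrality=integrality,
        options=opts,
    )
    status_map = {0: "optimal", 1: "limit", 2: "infeasible", 3: "unbounded"}
    status = status_map.get(res.status, "error")
    out = {"status": status}
    if res.x is not None and status == "optimal":
        out["objective"] = float(sign * res.fun)
        out["x"] = [float(v) for v in res.x]
    return out


def main(infile, outfile):
    with open(infile) as fh:
        payload = json.load(fh)
    results = []
    for p in payload["problems"]:
        try:
            results.append(solve_one(p))
        except Exception as exc:  # surfaced to R as a solver error
            results.append({"status": "error", "message": str(exc)})
    with open(outfile, "w") as fh:
        json.dump({"results": results}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
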