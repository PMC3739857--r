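"""Batch LP oracle used by the R test oracles.

Reads a JSON job {"S": [[...]], "problems": [{obj, lb, ub, maximize,
Ageq?, bgeq?}, ...]} and solves each problem with scipy's HiGHS interface:
max/min obj'v subject to S v = 0, Ageq v >= bgeq, lb <= v <= ub.
Writes a JSON list of {status, objective, solution}.

This is deliberately a different solver and a dense formulation, so it can
serve as an independent cross-check of the package's own simplex.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def main(inp, outp):
    with open(inp) as fh:
        job = json.load(fh)
    n = int(job["n"])
    S = np.array(job.get("S") or [], dtype=float)
    if S.size == 0:
        S = S.reshape((0, n))
    out = []
    for p in job["problems"]:
        c = np.asarray(p["obj"], dtype=float)
        lb = np.asarray(p["lb"], dtype=float)
        ub = np.asarray(p["ub"], dtype=float)
        sense = -1.0 if p["maximize"] else 1.0
        A_ub = b_ub = None
        if p.get("Ageq"):
            A_ub = -np.array(p["Ageq"], dtype=float).reshape((-1, n))
            b_ub = -np.asarray(p["bgeq"], dtype=float)
        res = linprog(
            sense * c,
            A_eq=S if S.shape[0] else None,
            b_eq=np.zeros(S.shape[0]) if S.shape[0] else None,
            A_ub=A_ub, b_ub=b_ub,
            bounds=list(zip(lb, ub)), method="highs")
        if res.status == 0:
            out.append({"status": "optimal",
                        "objective": float(c @ res.x),
                        "solution": [float(x) for x in res.x]})
        elif res.status == 2:
            out.append({"status": "infeasible"})
        elif res.status == 3:
            out.append({"status": "unbounded"})
        else:
            out.append({"status": "failed"})
    with open(outp, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
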