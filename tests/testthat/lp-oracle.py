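"""Independent producibility-screen oracle.

Re-derives the screen from a model JSON with scipy.optimize.linprog (HiGHS),
using fluxes directly as bounded variables with an equality steady-state
matrix -- a formulation unrelated to the R implementation under test.

Usage: python lp-oracle.py model.json config.json out.json
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def load(path):
    with open(path) as fh:
        return json.load(fh)


def main(model_path, cfg_path, out_path):
    model = load(model_path)
    cfg = load(cfg_path)
    rxns = model["reactions"]
    rids = [r["id"] for r in rxns]
    mets = sorted({m for r in rxns for m in r["stoich"]})
    S = np.zeros((len(mets), len(rxns)))
    for j, r in enumerate(rxns):
        for m, c in r["stoich"].items():
            S[mets.index(m), j] = c
    lb = np.array([r["lb"] for r in rxns], float)
    ub = np.array([r["ub"] for r in rxns], float)
    exchanges = dict(model.get("exchanges", {}))
    biomass = rids.index(model["biomass"])

    def solve(c, S, lb, ub, extra=None):
        A_ub, b_ub = None, None
        if extra is not None:
            A_ub = -extra[0][None, :]  # a.v >= rhs  ->  -a.v <= -rhs
            b_ub = np.array([-extra[1]])
        res = linprog(-c, A_ub=A_ub, b_ub=b_ub, A_eq=S,
                      b_eq=np.zeros(S.shape[0]),
                      bounds=list(zip(lb, ub)), method="highs")
        return (-res.fun, res.status) if res.success else (None, res.status)

    medium = dict(cfg.get("medium", {}))
    if cfg.get("remove_glucose", True):
        medium.pop(cfg.get("glucose_id", "glc__D"), None)

    results = []
    for source in cfg["sources"]:
        for ox_name, ox_rate in cfg["oxygen_levels"].items():
            l, u, Sx, rl = lb.copy(), ub.copy(), S, list(rids)
            rx_index = {r: i for i, r in enumerate(rl)}
            exch = dict(exchanges)

            def add_exchange(met, prefix="EX_"):
                nonlocal Sx, l, u
                if met in exch:
                    return exch[met]
                rid = prefix + met
                col = np.zeros((Sx.shape[0], 1))
                if met not in mets:
                    raise SystemExit(f"unknown metabolite {met}")
                col[mets.index(met), 0] = -1
                Sx = np.hstack([Sx, col])
                l = np.append(l, 0.0)
                u = np.append(u, 1000.0)
                rl.append(rid)
                rx_index[rid] = len(rl) - 1
                exch[met] = rid
                return rid

            for met, rid in exch.items():
                l[rx_index[rid]] = 0.0
            for met, rate in medium.items():
                rid = add_exchange(met)
                l[rx_index[rid]] = -rate
            rid = add_exchange(cfg.get("oxygen_id", "o2"))
            l[rx_index[rid]] = -ox_rate
            rid = add_exchange(source)
            l[rx_index[rid]] = -cfg["source_uptake"]

            cvec = np.zeros(len(rl))
            cvec[biomass] = 1.0
            mu, status = solve(cvec, Sx, l, u)
            for target in cfg["targets"]:
                prefix = "EX_" if target in exch else "DM_"
                trid = add_exchange(target, prefix)
                cobj = np.zeros(len(rl))
                cobj[rx_index[trid]] = 1.0
                extra = None
                if mu is not None and mu > 1e-9:
                    a = np.zeros(len(rl))
                    a[biomass] = 1.0
                    extra = (a, cfg["growth_fraction"] * mu)
                # biomass objective vector may be shorter than current Sx
                val, st = solve(cobj, Sx, l, u, extra)
                flux = max(val, 0.0) if val is not None else 0.0
                results.append({
                    "source": source, "target": target, "oxygen": ox_name,
                    "max_flux": flux,
                    "producible": bool(flux > cfg["epsilon"]),
                })
    with open(out_path, "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main(*sys.argv[1:4])
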