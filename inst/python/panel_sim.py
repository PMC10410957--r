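"""Coalescent haplotype-panel simulator (msprime driver).

Writes a plain-text panel: a '#meta {...}' JSON header line with the mean
pairwise coalescence time E_T2 (generations), then one line of site
positions (bp), then one line per biallelic segregating site with 0/1
alleles for the n haploid samples.

Demographies:
  constant        one population of size --ne
  african_growth  single-population African history: ancestral size 7310
                  until 5920 generations ago, then 14474, with exponential
                  growth of 1.66%/generation starting ~205 generations ago
                  (the African component of a standard human out-of-Africa
                  model; generation time 25 y).
"""

import argparse
import json

import msprime
import numpy as np

AFR_N_ANC = 7310.0
AFR_N_AF = 14474.0
AFR_T_AF = 148000.0 / 25.0     # 5920 generations
AFR_T_GROWTH = 5115.0 / 25.0   # ~204.6 generations
AFR_RATE = 0.0166


def african_demography():
    n0 = AFR_N_AF * np.exp(AFR_RATE * AFR_T_GROWTH)
    dem = msprime.Demography()
    dem.add_population(name="AFR", initial_size=n0, growth_rate=AFR_RATE)
    dem.add_population_parameters_change(time=AFR_T_GROWTH, initial_size=AFR_N_AF,
                                         growth_rate=0.0)
    dem.add_population_parameters_change(time=AFR_T_AF, initial_size=AFR_N_ANC)
    return dem


def pop_size_at(t):
    if t >= AFR_T_AF:
        return AFR_N_ANC
    if t >= AFR_T_GROWTH:
        return AFR_N_AF
    n0 = AFR_N_AF * np.exp(AFR_RATE * AFR_T_GROWTH)
    return n0 * np.exp(-AFR_RATE * t)


def expected_t2(demography, ne):
    if demography == "constant":
        return 2.0 * ne
    # numerical integration of the pair-coalescence survival function
    tmax = 30.0 * AFR_N_ANC
    t = np.linspace(0.0, tmax, 600000)
    rate = 1.0 / (2.0 * np.array([pop_size_at(x) for x in t]))
    cum = np.concatenate([[0.0], np.cumsum((rate[1:] + rate[:-1]) / 2.0 * np.diff(t))])
    surv = np.exp(-cum)
    return float(np.trapezoid(surv, t))


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--n", type=int, required=True)
    ap.add_argument("--length", type=float, required=True)
    ap.add_argument("--mu", type=float, required=True)
    ap.add_argument("--rho", type=float, required=True)
    ap.add_argument("--ne", type=float, default=1.0)
    ap.add_argument("--demography", choices=["constant", "african_growth"],
                    default="constant")
    ap.add_argument("--seed", type=int, required=True)
    ap.add_argument("--out", required=True)
    args = ap.parse_args()

    # simulate diploid individuals so population sizes follow the usual
    # diploid convention (pair coalescence rate 1/(2N)); use the first
    # n haplotype columns
    n_ind = (args.n + 1) // 2
    kwargs = dict(samples=n_ind, ploidy=2, sequence_length=args.length,
                  recombination_rate=args.rho, random_seed=args.seed)
    if args.demography == "constant":
        kwargs["population_size"] = args.ne
    else:
        kwargs["demography"] = african_demography()
    ts = msprime.sim_ancestry(**kwargs)
    mts = msprime.sim_mutations(ts, rate=args.mu, random_seed=args.seed + 1,
                                model=msprime.BinaryMutationModel())

    rows = []
    positions = []
    for var in mts.variants():
        gt = var.genotypes[: args.n]
        if len(var.alleles) != 2:
            continue
        if gt.min() == gt.max():
            continue
        positions.append(var.site.position)
        rows.append(gt.astype(np.int8))

    meta = {"E_T2": expected_t2(args.demography, args.ne),
            "n_sites": len(rows), "n_samples": args.n}
    with open(args.out, "w") as fh:
        fh.write("#meta " + json.dumps(meta) + "\n")
        fh.write(" ".join(f"{p:.1f}" for p in positions) + "\n")
        for row in rows:
            fh.write(" ".join(map(str, row)) + "\n")


if __name__ == "__main__":
    main()
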