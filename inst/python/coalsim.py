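"""Coalescent simulation driver for the introscan R package.

Reads a JSON job description, simulates two-population samples with msprime
(optionally with a pulse admixture event, continuous migration, or an
unsampled ghost donor population), and writes:
  * an ms-format file (one "//" block per replicate, positions as fractions
    of the window length), and
  * a tab-separated truth table recording, per replicate, the realized
    (T_M, P_M), the sampled haplotypes carrying migrant material, and the
    introgressed tract intervals in bp.

Scaling conventions (ms-compatible): the job supplies theta = 4*N0*mu*L and
rho = 4*N0*r*L for a diploid reference size N0, with times in units of 4*N0
generations and continuous migration rates in units of 4*N0*m. Samples are
haploid genomes, so msprime population sizes are set to 2*N0 (pairwise
coalescence rate 1/(2*N0) per generation, matching ms).
"""

import json
import random
import sys

import msprime
import numpy as np


MAX_SEED = 2**31 - 2
ATTEMPT_CAP = 10000


def build_demography(model, tm_gen=None, pm=None, direction=None):
    """direction: 'mig12' forward-time 1->2 pulse, 'mig21', 'ghost1'/'ghost2'
    (ghost donor into population 1 or 2), or None."""
    N0 = model["N0"]
    td_gen = model["td"] * 4.0 * N0 if model.get("td") else None
    dem = msprime.Demography()
    sizes = model.get("sizes", {})

    def add_pop(name, default=2.0 * N0):
        entry = sizes.get(name)
        if entry is None:
            dem.add_population(name=name, initial_size=default)
        elif isinstance(entry, (int, float)):
            dem.add_population(name=name, initial_size=2.0 * entry)
        else:  # [present, at_split] exponential size change
            present, at_split = 2.0 * entry[0], 2.0 * entry[1]
            import math
            g = math.log(present / at_split) / td_gen
            dem.add_population(name=name, initial_size=present, growth_rate=g)

    if td_gen is None:  # panmictic control
        add_pop("p1")
        return dem, None

    add_pop("p1")
    add_pop("p2")
    ghost = model.get("ghost", False) or (direction or "").startswith("ghost")
    if ghost:
        add_pop("ghost")
    add_pop("anc")

    m12 = model.get("m12", 0.0)  # forward-time 1->2, units of 4*N0*m
    m21 = model.get("m21", 0.0)
    if m12 > 0:  # backwards: lineages now in p2 trace back into p1
        dem.set_migration_rate(source="p2", dest="p1", rate=m12 / (4.0 * N0))
    if m21 > 0:
        dem.set_migration_rate(source="p1", dest="p2", rate=m21 / (4.0 * N0))

    if direction in ("mig12", "mig21", "ghost1", "ghost2"):
        recipient = {"mig12": "p2", "mig21": "p1",
                     "ghost1": "p1", "ghost2": "p2"}[direction]
        donor = {"mig12": "p1", "mig21": "p2",
                 "ghost1": "ghost", "ghost2": "ghost"}[direction]
        dem.add_mass_migration(time=tm_gen, source=recipient, dest=donor,
                               proportion=pm)
    derived = ["p1", "p2"] + (["ghost"] if ghost else [])
    dem.add_population_split(time=td_gen, derived=derived, ancestral="anc")
    return dem, td_gen


def simulate_once(model, rep, seed_anc, seed_mut):
    N0, L = model["N0"], model["L"]
    tm_gen = rep["tm"] * 4.0 * N0 if rep.get("tm") is not None else None
    dem, td_gen = build_demography(model, tm_gen=tm_gen, pm=rep.get("pm"),
                                   direction=rep.get("direction"))
    if td_gen is None:
        samples = {"p1": model["n1"] + model["n2"]}
    else:
        samples = {"p1": model["n1"], "p2": model["n2"]}
    ts = msprime.sim_ancestry(
        samples=samples, ploidy=1, demography=dem, sequence_length=L,
        recombination_rate=model["rho"] / (4.0 * N0 * L),
        record_migrations=True, random_seed=seed_anc)
    ts = msprime.sim_mutations(
        ts, rate=model["theta"] / (4.0 * N0 * L), random_seed=seed_mut,
        model=msprime.BinaryMutationModel(), discrete_genome=False)
    return ts, tm_gen, td_gen


def pulse_truth(ts, tm_gen, n_samples):
    """Migrant sample ids and merged tract intervals (bp floats) for the
    pulse recorded at time tm_gen."""
    recs = [m for m in ts.migrations() if m.time == tm_gen]
    if not recs:
        return [], []
    migrants = set()
    pieces = []
    for tree in ts.trees():
        tl, tr = tree.interval
        for m in recs:
            if m.left < tr and m.right > tl:
                leaves = [u for u in tree.leaves(m.node) if u < n_samples]
                if leaves:
                    migrants.update(leaves)
                    pieces.append((max(m.left, tl), min(m.right, tr)))
    pieces.sort()
    merged = []
    for a, b in pieces:
        if merged and a <= merged[-1][1]:
            merged[-1][1] = max(merged[-1][1], b)
        else:
            merged.append([a, b])
    return sorted(migrants), merged


def any_migrant(ts, td_gen):
    mig = ts.tables.migrations
    return bool(len(mig)) and bool((mig.time < td_gen).any())


def ms_block(ts, L, out):
    out.write("//\n")
    out.write("segsites: %d\n" % ts.num_sites)
    if ts.num_sites == 0:
        out.write("\n")
        return
    pos = [site.position / L for site in ts.sites()]
    out.write("positions: " + " ".join("%.8f" % p for p in pos) + "\n")
    geno = ts.genotype_matrix()  # sites x samples
    for j in range(geno.shape[1]):
        out.write("".join("1" if g else "0" for g in geno[:, j]) + "\n")


def splice_contig(model, rep, rng):
    """1 Mb-style contig: pulse admixture restricted to the central segment.
    The two flanks and the centre are simulated as independent chunks under
    the same demography (pulse active only in the centre) and concatenated."""
    L = model["L"]
    c0, c1 = rep.get("center", [int(0.45 * L), int(0.55 * L)])
    ## simulate the pulse-free flanks in sub-chunks (ARG cost grows
    ## superlinearly with rho; the extra free-recombination breakpoints are
    ## negligible at these recombination rates)
    max_chunk = int(rep.get("chunk_bp", 100000))
    chunks = []
    for (a, b) in ((0, c0), (c0, c1), (c1, L)):
        if (a, b) == (c0, c1):
            ## pulse only in the centre, and only for introgression reps
            chunks.append((a, b, rep.get("direction")
                           if rep.get("tm") is not None else None))
            continue
        x = a
        while x < b:
            y = min(x + max_chunk, b)
            chunks.append((x, y, None))
            x = y
    blocks = []
    truth_mig, truth_tracts = set(), []
    n_samples = model["n1"] + model["n2"]
    for (a, b, direction) in chunks:
        sub = dict(model)
        frac = (b - a) / L
        sub["L"] = b - a
        sub["theta"] = model["theta"] * frac
        sub["rho"] = model["rho"] * frac
        sub_rep = dict(rep)
        sub_rep["direction"] = direction
        if direction is None:
            sub_rep["tm"] = None
        ts, tm_gen, td_gen = simulate_once(
            sub, sub_rep, rng.randint(1, MAX_SEED), rng.randint(1, MAX_SEED))
        blocks.append((a, b, ts))
        if direction is not None:
            mig, tracts = pulse_truth(ts, tm_gen, n_samples)
            truth_mig.update(mig)
            truth_tracts += [[x + a, y + a] for x, y in tracts]
    return blocks, sorted(truth_mig), truth_tracts


def contig_ms_block(blocks, L, out):
    pos, rows = [], None
    for (a, b, ts) in blocks:
        if ts.num_sites == 0:
            continue
        pos += [(a + site.position) / L for site in ts.sites()]
        geno = ts.genotype_matrix()
        rows = geno if rows is None else np.vstack([rows, geno])
    out.write("//\n")
    n_sites = 0 if rows is None else rows.shape[0]
    out.write("segsites: %d\n" % n_sites)
    if n_sites == 0:
        out.write("\n")
        return
    out.write("positions: " + " ".join("%.8f" % p for p in pos) + "\n")
    for j in range(rows.shape[1]):
        out.write("".join("1" if g else "0" for g in rows[:, j]) + "\n")


def main(job_path):
    with open(job_path) as fh:
        job = json.load(fh)
    model = job["model"]
    reps = job["reps"]
    rng = random.Random(job["seed"])
    n_samples = model["n1"] + model["n2"]
    with open(job["out_ms"], "w") as ms_out, open(job["out_truth"], "w") as tr:
        ms_out.write("introscan-coalsim %d reps\nseed: %d\n" %
                     (len(reps), job["seed"]))
        tr.write("rep\tlabel\ttm\tpm\tn_migrant\tmigrants\ttracts\tsegsites\n")
        for i, rep in enumerate(reps):
            rep_rng = random.Random(rng.randint(1, MAX_SEED))
            label = rep.get("label", "noMig")
            if rep.get("type") == "contig":
                blocks, migrants, tracts = splice_contig(model, rep, rep_rng)
                contig_ms_block(blocks, model["L"], ms_out)
                nseg = sum(ts.num_sites for (_, _, ts) in blocks)
            else:
                attempts = 0
                while True:
                    ts, tm_gen, td_gen = simulate_once(
                        model, rep, rep_rng.randint(1, MAX_SEED),
                        rep_rng.randint(1, MAX_SEED))
                    if not rep.get("condition", False):
                        break
                    if tm_gen is not None:
                        ok = len([m for m in ts.migrations()
                                  if m.time == tm_gen]) > 0
                    else:
                        ok = any_migrant(ts, td_gen)
                    attempts += 1
                    if ok or attempts >= ATTEMPT_CAP:
                        break
                if rep.get("direction") and rep.get("tm") is not None:
                    migrants, tracts = pulse_truth(ts, tm_gen, n_samples)
                    n_migrant = len(migrants)
                elif td_gen is not None and any_migrant(ts, td_gen):
                    # continuous migration: per-replicate flag only
                    migrants, tracts, n_migrant = [], [], 1
                else:
                    migrants, tracts, n_migrant = [], [], 0
                ms_block(ts, model["L"], ms_out)
                nseg = ts.num_sites
            if rep.get("type") == "contig":
                n_migrant = len(migrants)
            tr.write("%d\t%s\t%s\t%s\t%d\t%s\t%s\t%d\n" % (
                i + 1, label,
                "" if rep.get("tm") is None else "%g" % rep["tm"],
                "" if rep.get("pm") is None else "%g" % rep["pm"],
                n_migrant,
                ",".join(str(m) for m in migrants) if migrants else ".",
                ";".join("%d-%d" % (int(a), -int(-b // 1)) for a, b in tracts)
                if tracts else ".",
                nseg))


if __name__ == "__main__":
    main(sys.argv[1])
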