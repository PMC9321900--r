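# Independent coalescent-with-recombination oracle (msprime).
# Simulates a two-population split in mutation-scaled time (time unit =
# expected substitutions/site; ploidy 1 with population size theta/2 gives
# pairwise coalescence rate 2/theta) and prints, per replicate:
#   TMRCA at site 0, number of ARG recombination events.
# Usage: python msprime_twopop.py theta tau rho_per_kb n_sites S nreps seed
import sys

import msprime

theta, tau, rho, n, S, nreps, seed = (float(sys.argv[1]), float(sys.argv[2]),
                                      float(sys.argv[3]), int(sys.argv[4]),
                                      int(sys.argv[5]), int(sys.argv[6]),
                                      int(sys.argv[7]))
dem = msprime.Demography()
dem.add_population(name="A", initial_size=theta / 2)
dem.add_population(name="B", initial_size=theta / 2)
dem.add_population(name="R", initial_size=theta / 2)
dem.add_population_split(time=tau, derived=["A", "B"], ancestral="R")
r = (rho / 1000.0) / theta
for ts in msprime.sim_ancestry({"A": S, "B": S}, demography=dem, ploidy=1,
                               sequence_length=n, recombination_rate=r,
                               discrete_genome=True, record_full_arg=True,
                               num_replicates=nreps, random_seed=seed):
    t0 = ts.first()
    tmrca = t0.time(t0.root)
    n_re = sum(1 for nd in ts.nodes()
               if nd.flags & msprime.NODE_IS_RE_EVENT) // 2
    print(f"{tmrca:.10g},{n_re}")
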