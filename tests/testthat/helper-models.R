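# Small models built in code for unit and oracle tests.

toy_chain <- function() parseNetworkModel(c(
  "@met A carbons=3 source",
  "@met B carbons=3",
  "@met C carbons=3",
  "@met S carbons=3 sink",
  "r1: 1 A (abc) -> 1 B (abc)",
  "r2: 1 B (abc) -> 1 C (abc)",
  "r3: 1 C (abc) -> 1 S (abc)"))

toy_split <- function() parseNetworkModel(c(
  "@met A carbons=3 source",
  "@met B carbons=2",
  "@met C carbons=1",
  "@met D carbons=3",
  "@met S carbons=3 sink",
  "r1: 1 A (abc) -> 1 B (ab) + 1 C (c)",
  "r2: 1 B (ab) + 1 C (c) -> 1 D (abc)",
  "r3: 1 D (abc) -> 1 S (abc)"))

# reversible + symmetric + convolution features in <= 4 carbons
toy_rich <- function() parseNetworkModel(c(
  "@met IN carbons=1 source",
  "@met P carbons=2",
  "@met Q carbons=2 symmetric=yes",
  "@met R carbons=4",
  "@met S4 carbons=4 sink",
  "@met S2 carbons=2 sink",
  "up: 1 IN (a) + 1 IN (b) -> 1 P (ab)",
  "iso: 1 P (ab) -> 1 Q (ab) | reversible=yes",
  "join: 1 P (ab) + 1 Q (cd) -> 1 R (abcd)",
  "outr: 1 R (abcd) -> 1 S4 (abcd)",
  "outq: 1 Q (ab) -> 1 S2 (ab)"))

toy_rich_flux <- function() {
  ## P and Q balances force join = (up - outq)/2
  v <- steadyStateFlux(toy_rich(), c(up = 3, outq = 0.5))
  FluxState(net = v, exch = c(iso = 2),
            pools = c(P = 0.4, Q = 0.7, R = 0.3))
}

toy_diamond <- function() parseNetworkModel(c(
  "@met A carbons=1 source",
  "@met B carbons=1",
  "@met C carbons=1",
  "@met D carbons=1",
  "@met S carbons=1 sink",
  "r0: 1 A (a) -> 1 B (a)",
  "r1: 1 B (a) -> 1 C (a)",
  "r2: 1 B (a) -> 1 D (a)",
  "r3: 1 C (a) -> 1 D (a)",
  "r4: 1 D (a) -> 1 S (a)"))

# one-pool tracer washin, closed form 1 - exp(-v t / c)
toy_pool <- function() parseNetworkModel(c(
  "@met CO2in carbons=1 source",
  "@met B carbons=1",
  "@met S carbons=1 sink",
  "in: 1 CO2in (a) -> 1 B (a)",
  "out: 1 B (a) -> 1 S (a)"))
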