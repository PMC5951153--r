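# Synthetic parameterization of a Raf -> MEK -> ERK cascade of the kind
# introduced by Sturm et al. (negative feedback intact).  Structure: RasGTP
# activates Raf (Michaelis-Menten, inhibited by ppERK feedback); active Raf
# distributively doubly phosphorylates MEK (shared kinase, competitive
# substrates, dedicated phosphatases per site); doubly phosphorylated MEK
# phosphorylates ERK on two sites with first-order (unsaturated) kinetics,
# while a single shared ERK phosphatase works near saturation on both
# phospho-forms.  The shared saturated phosphatase makes the ERK cycle
# bistable, so doubly phosphorylated ERK (pERK, the output) jumps between a
# near-zero and a near-pool-sized state; because the switching threshold
# scales inversely with the ERK pool and the MEK-tier drive scales with the
# MEK pool, cells with more MEK or ERK activate at lower input doses.
#
# Rate constants are an in-house calibration (not transcribed from any
# published supplement): the activation transition is centered near an input
# dose of 2^11 concentration units, and the terminal-pERK threshold of 17
# falls between the low (~0-5) and high (~70-100) modes.
# Units: concentrations in arbitrary model units; time dimensionless.
rates:
  kc1: 1.2e-4   # Raf activation by RasGTP (per unit RasGTP)
  Km1: 20.0
  Ki: 500.0     # feedback inhibition constant (ppERK units)
  kc2: 0.3      # Raf* dephosphorylation (phosphatase P1)
  Km2: 20.0
  kc3: 0.25     # MEK phosphorylation by Raf* (both sites, competitive)
  Km3: 300.0
  kc4: 10.0     # ppMEK -> pMEK (phosphatase P2a)
  Km4: 300.0
  kc4b: 10.0    # pMEK -> MEK (phosphatase P2b)
  Km4b: 300.0
  kc5: 10.0     # ERK -> pERK by ppMEK (first-order in substrate)
  kc5b: 90.0    # pERK -> ppERK by ppMEK
  Km5: 500.0
  kc6: 10.0     # ppERK -> pERK (shared phosphatase P3, saturated)
  Km6: 0.5
  kc7: 30.0     # pERK -> ERK (shared phosphatase P3, saturated)
  Km7: 2.0
phosphatases:
  P1: 1.0       # Raf* phosphatase
  P2a: 1.0      # ppMEK phosphatase
  P2b: 1.0      # pMEK phosphatase
  P3: 1.0       # shared ERK phosphatase (MKP-like)
totals:
  Raf: 100.0
  MEK: 120.0
  ERK: 100.0
input_dose: 2352.5   # RasGTP, ~2^11.2 model units (intermediate stimulus)
t_end: 150.0
perk_threshold: 17.0
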