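# Central-carbon fixture network: glycolysis from hexose sources, the
# pyruvate node, the TCA cycle with anaplerosis (pyruvate carboxylase) and
# cataplerosis (malic enzyme), and the 3PG -> serine -> glycine branch.
# Carbon fates are the textbook ones at mass-isotopomer resolution: hexose
# cleavage retains a three-carbon unit, decarboxylations lose one carbon,
# citrate synthase condenses acetyl-CoA (2C) with oxaloacetate (4C).
# Dietary inflows (serine, acetyl units) and CO2 enter unlabeled; the
# uptake-normalizing and dietary-inflow equality constraints pin the
# absolute flux scale. Bounds are uniform and deliberately slack.
pools:
  - {id: GLC,   carbons: 6, role: source,   measured: false}
  - {id: FRC,   carbons: 6, role: source,   measured: false}
  - {id: CO2,   carbons: 1, role: source,   measured: false}
  - {id: SERX,  carbons: 3, role: source,   measured: false}
  - {id: ACE,   carbons: 2, role: source,   measured: false}
  - {id: GAP,   carbons: 3, role: internal, measured: true}
  - {id: 3PG,   carbons: 3, role: internal, measured: true}
  - {id: PEP,   carbons: 3, role: internal, measured: true}
  - {id: PYR,   carbons: 3, role: internal, measured: true}
  - {id: SER,   carbons: 3, role: internal, measured: true}
  - {id: ACCOA, carbons: 2, role: internal, measured: false}
  - {id: CIT,   carbons: 6, role: internal, measured: true}
  - {id: AKG,   carbons: 5, role: internal, measured: true}
  - {id: SUC,   carbons: 4, role: internal, measured: true}
  - {id: MAL,   carbons: 4, role: internal, measured: true}
  - {id: OAC,   carbons: 4, role: internal, measured: false}
  - {id: LAC,   carbons: 3, role: sink,     measured: true}
  - {id: GLY,   carbons: 2, role: sink,     measured: true}
reactions:
  - id: r_glc
    substrates: [GLC]
    product: GAP
    carbon_map: [[1, 1], [1, 2], [1, 3]]
    lost: [[1, 4], [1, 5], [1, 6]]
  - id: r_frc
    substrates: [FRC]
    product: GAP
    carbon_map: [[1, 1], [1, 2], [1, 3]]
    lost: [[1, 4], [1, 5], [1, 6]]
  - id: r_gapdh
    substrates: [GAP]
    product: 3PG
    carbon_map: [[1, 1], [1, 2], [1, 3]]
  - id: r_eno
    substrates: [3PG]
    product: PEP
    carbon_map: [[1, 1], [1, 2], [1, 3]]
  - id: r_pk
    substrates: [PEP]
    product: PYR
    carbon_map: [[1, 1], [1, 2], [1, 3]]
  - id: r_ldh
    substrates: [PYR]
    product: LAC
    carbon_map: [[1, 1], [1, 2], [1, 3]]
  - id: r_pgser
    substrates: [3PG]
    product: SER
    carbon_map: [[1, 1], [1, 2], [1, 3]]
  - id: r_serin
    substrates: [SERX]
    product: SER
    carbon_map: [[1, 1], [1, 2], [1, 3]]
  - id: r_shmt
    substrates: [SER]
    product: GLY
    carbon_map: [[1, 1], [1, 2]]
    lost: [[1, 3]]
  - id: r_pdh
    substrates: [PYR]
    product: ACCOA
    carbon_map: [[1, 2], [1, 3]]
    lost: [[1, 1]]
  - id: r_acein
    substrates: [ACE]
    product: ACCOA
    carbon_map: [[1, 1], [1, 2]]
  - id: r_cs
    substrates: [ACCOA, OAC]
    product: CIT
    carbon_map: [[1, 1], [1, 2], [2, 1], [2, 2], [2, 3], [2, 4]]
  - id: r_idh
    substrates: [CIT]
    product: AKG
    carbon_map: [[1, 1], [1, 2], [1, 3], [1, 4], [1, 5]]
    lost: [[1, 6]]
  - id: r_kgdh
    substrates: [AKG]
    product: SUC
    carbon_map: [[1, 2], [1, 3], [1, 4], [1, 5]]
    lost: [[1, 1]]
  - id: r_sdh
    substrates: [SUC]
    product: MAL
    carbon_map: [[1, 1], [1, 2], [1, 3], [1, 4]]
  - id: r_mdh
    substrates: [MAL]
    product: OAC
    carbon_map: [[1, 1], [1, 2], [1, 3], [1, 4]]
  - id: r_pc
    substrates: [PYR, CO2]
    product: OAC
    carbon_map: [[1, 1], [1, 2], [1, 3], [2, 1]]
  - id: r_me
    substrates: [MAL]
    product: PYR
    carbon_map: [[1, 1], [1, 2], [1, 3]]
    lost: [[1, 4]]
bounds:
  default: [0, 200]
extra_constraints:
  # hexose uptake normalized to 100 relative flux units
  - {reactions: [r_glc, r_frc], coefficients: [1, 1], rhs: 100}
  # fixed dietary serine inflow
  - {reactions: [r_serin], coefficients: [1], rhs: 10}
  # fixed dietary acetyl-unit inflow
  - {reactions: [r_acein], coefficients: [1], rhs: 10}
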