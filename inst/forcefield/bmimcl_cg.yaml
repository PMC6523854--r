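# Default coarse-grained force-field registry for [bmim][Cl] + cellulose + water.
#
# Site types I1/I2 (imidazolium ring beads), I3 (methyl), CT (butyl tail) and
# CI (chloride) carry the published Mie n-m parameters for the five-site
# ionic-liquid model. Water is rigid SPC/E (12-6 oxygen site, standard SPC/E
# charges). The six cellulose bead types per cellobiose (C11/C14/C16 on the
# first glucose, C21/C24/C26 on the second, named by the mapped ring carbon)
# are package defaults: well depths and small partial charges encode hydroxyl
# accessibility (C16/C26 carry the reactive primary hydroxyl, C11/C24 weaker
# secondary hydroxyls, C14/C21 none; bead charges sum to zero per glucose).
#
# Cation charges are not part of the published parameter set; the default
# places +0.5 e on each ring bead (tails neutral) for a net +1 cation,
# balanced by -1 on chloride. Override per site type as needed.
#
# Bonded reference geometry (bond lengths, angles, dihedral phases) is derived
# from the molecule template coordinates below, so every builder starts each
# molecule at its bonded-energy minimum; only force constants are listed.
meta:
  name: bmimcl-cellulose-cg
  units: {energy: kcal/mol, length: angstrom, mass: g/mol, charge: e, angle: degree}

mixing:
  exponent_rule: arithmetic     # arithmetic | fixed
  fixed_exponents: [9, 6]

exclusions:
  policy: "1-3"                 # exclude 1-2 and 1-3 nonbonded pairs
  scale14: 1.0                  # scale factor for 1-4 pairs

site_types:
  I1:  {mass: 33.540, charge:  0.5,    epsilon: 0.375, "n": 9,  m: 6, r0: 4.693}
  I2:  {mass: 33.530, charge:  0.5,    epsilon: 0.345, "n": 9,  m: 6, r0: 4.693}
  I3:  {mass: 15.035, charge:  0.0,    epsilon: 0.199, "n": 9,  m: 6, r0: 4.120}
  CT:  {mass: 57.115, charge:  0.0,    epsilon: 0.469, "n": 9,  m: 6, r0: 5.249}
  CI:  {mass: 35.453, charge: -1.0,    epsilon: 0.148, "n": 12, m: 6, r0: 4.232}
  OW:  {mass: 15.999, charge: -0.8476, epsilon: 0.1553, "n": 12, m: 6, sigma: 3.166}
  HW:  {mass:  1.008, charge:  0.4238, epsilon: 0.0}
  C11: {mass: 54.050, charge:  0.10,   epsilon: 0.45, "n": 9,  m: 6, r0: 5.2}
  C14: {mass: 54.040, charge: -0.25,   epsilon: 0.20, "n": 9,  m: 6, r0: 5.2}
  C16: {mass: 54.050, charge:  0.15,   epsilon: 0.80, "n": 9,  m: 6, r0: 4.7}
  C21: {mass: 54.050, charge: -0.25,   epsilon: 0.20, "n": 9,  m: 6, r0: 5.2}
  C24: {mass: 54.040, charge:  0.10,   epsilon: 0.45, "n": 9,  m: 6, r0: 5.2}
  C26: {mass: 54.050, charge:  0.15,   epsilon: 0.80, "n": 9,  m: 6, r0: 4.7}

molecules:
  bmim:
    species: bmim
    sites:
      - {id: I3, type: I3}
      - {id: I1, type: I1}
      - {id: I2, type: I2}
      - {id: CT, type: CT}
    # Bead separations reflect the mapping: the two ring beads are halves of
    # one fused imidazolium ring (centroids ~2.3 A apart), the methyl sits
    # ~2.5 A from its ring bead and the butyl centroid ~3.4 A from the other;
    # backbone angles of 140 degrees. These separations set the cation's
    # molar volume and were calibrated against the model's reported
    # atmospheric liquid density.
    coords:
      I3: [-2.500000, 0.000000, 0.0]
      I1: [ 0.000000, 0.000000, 0.0]
      I2: [ 1.761901, 1.478412, 0.0]
      CT: [ 5.161901, 1.478412, 0.0]
    bonds:
      - {ij: [I3, I1], k: 60.0}
      - {ij: [I1, I2], k: 80.0}
      - {ij: [I2, CT], k: 60.0}
    bends:
      - {ijk: [I3, I1, I2], k: 15.0}
      - {ijk: [I1, I2, CT], k: 15.0}
    dihedrals:
      - {ijkl: [I3, I1, I2, CT], amp: 1.0, mult: 1}

  chloride:
    species: chloride
    sites:
      - {id: CI, type: CI}
    coords:
      CI: [0.0, 0.0, 0.0]

  water:
    species: water
    rigid: water
    sites:
      - {id: O,  type: OW}
      - {id: H1, type: HW}
      - {id: H2, type: HW}
    coords:
      O:  [ 0.0000000, 0.0, 0.0000000]
      H1: [ 0.8164966, 0.0, 0.5773503]
      H2: [-0.8164966, 0.0, 0.5773503]

  cellobiose:
    species: cellulose
    repeat: true
    z_period: 10.2
    sites:
      - {id: C14, type: C14}
      - {id: C11, type: C11}
      - {id: C16, type: C16}
      - {id: C24, type: C24}
      - {id: C21, type: C21}
      - {id: C26, type: C26}
    coords:
      C14: [ 0.0, 0.0, 0.00]
      C11: [ 0.6, 0.0, 2.55]
      C16: [-2.8, 0.0, 0.50]
      C24: [ 0.0, 0.0, 5.10]
      C21: [ 0.6, 0.0, 7.65]
      C26: [ 2.8, 0.0, 5.60]
    # A trailing "+" refers to the same site in the next repeat unit; the
    # per-unit template therefore owns 7 bonds, 4 bends and 8 dihedrals, and
    # the terminal unit of a finite chain drops the unit-spanning terms.
    bonds:
      - {ij: [C11, C14],    k: 80.0}
      - {ij: [C14, C16],    k: 80.0}
      - {ij: [C11, C16],    k: 40.0}
      - {ij: [C21, C24],    k: 80.0}
      - {ij: [C24, C26],    k: 80.0}
      - {ij: [C11, C24],    k: 80.0}
      - {ij: [C21, "C14+"], k: 80.0}
    bends:
      - {ijk: [C16, C14, C11],    k: 20.0}
      - {ijk: [C14, C11, C24],    k: 20.0}
      - {ijk: [C11, C24, C21],    k: 20.0}
      - {ijk: [C24, C21, "C14+"], k: 20.0}
    dihedrals:
      - {ijkl: [C16, C14, C11, C24],    amp: 0.8, mult: 1}
      - {ijkl: [C14, C11, C24, C21],    amp: 0.8, mult: 1}
      - {ijkl: [C14, C11, C24, C26],    amp: 0.8, mult: 1}
      - {ijkl: [C16, C11, C24, C21],    amp: 0.8, mult: 1}
      - {ijkl: [C11, C24, C21, "C14+"], amp: 0.8, mult: 1}
      - {ijkl: [C26, C24, C21, "C14+"], amp: 0.8, mult: 1}
      - {ijkl: [C24, C21, "C14+", "C11+"], amp: 0.8, mult: 1}
      - {ijkl: [C24, C21, "C14+", "C16+"], amp: 0.8, mult: 1}

water_model:
  dOH: 1.0
  dHH: 1.6329932

# Molar masses used by composition audits (g/mol).
species_masses:
  water: 18.015
  bmimcl: 174.673
  cellobiose: 324.28
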