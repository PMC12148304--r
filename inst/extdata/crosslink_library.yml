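# Crosslink type library (version 1).
# Lysine-derived collagen crosslinks: divalent types join exactly two residues,
# trivalent types exactly three. Residue codes are the modified-residue names
# used in assembled structures; reactive_atoms lists, per residue code, the
# side-chain atoms evaluated in inter-crosslink distance checks. Users may
# point crosslink_registry() at an extended copy of this file to add types.
version: 1
types:
  HLKNL:
    full_name: hydroxylysine-keto-norleucine
    valence: divalent
    residues: [L4Y, L5Y]
    reactive_atoms:
      L4Y: [NZ]
      L5Y: [NZ]
  LKNL:
    full_name: lysino-keto-norleucine
    valence: divalent
    residues: [L2Y, L3Y]
    reactive_atoms:
      L2Y: [NZ]
      L3Y: [NZ]
  PYD:
    full_name: hydroxylysyl-pyridinoline
    valence: trivalent
    residues: [LYX, LY2, LY3]
    reactive_atoms:
      LYX: [NZ]
      LY2: [NZ]
      LY3: [NZ]
  DPD:
    full_name: lysyl-pyridinoline (deoxypyridinoline)
    valence: trivalent
    residues: [LXX, LX2, LX3]
    reactive_atoms:
      LXX: [NZ]
      LX2: [NZ]
      LX3: [NZ]
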