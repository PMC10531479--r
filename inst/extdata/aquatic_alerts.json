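[
  {
    "alert_id": "TA662",
    "name": "aliphatic secondary and tertiary amines",
    "smarts": ["[NX3;H1,H0;!$([NX3][CX3]=[OX1]);!$([NX3]=*);!$([NX3][a]);!$([N+])]"],
    "note": "secondary/tertiary amine nitrogen not in amide, not on an aromatic ring"
  },
  {
    "alert_id": "TA665",
    "name": "primary alkyl amines",
    "smarts": ["[NX3;H2;!$([NX3][CX3]=[OX1]);!$([NX3][a]);!$([N+])][CX4]"],
    "note": "NH2 on a saturated carbon"
  },
  {
    "alert_id": "TA642",
    "name": "ammonium NH3+ groups",
    "smarts": ["[NX4+;H3]"],
    "note": "protonated primary amine"
  },
  {
    "alert_id": "TA628",
    "name": "beta-unsaturated nitro compounds",
    "smarts": ["[CX3]=[CX3][NX3+](=[OX1])[OX1-]",
               "[CX3]=[CX3][NX3](=[OX1])=[OX1]"],
    "note": "nitro group conjugated to a C=C double bond; charged and neutral depictions"
  },
  {
    "alert_id": "TA11521",
    "name": "4-nitrobenzene",
    "smarts": ["c1ccc(cc1)[NX3+](=[OX1])[OX1-]",
               "c1ccc(cc1)[NX3](=[OX1])=[OX1]"],
    "note": "nitro group on a benzene ring"
  },
  {
    "alert_id": "TA667",
    "name": "activated alkenes and alkynes",
    "smarts": ["[CX3]=[CX3][CX3]=[OX1]",
               "[CX3]=[CX3]C#N",
               "[CX3]=[CX3][NX3+](=[OX1])[OX1-]",
               "[CX3]=[CX3][SX4](=[OX1])=[OX1]",
               "C#C[CX3]=[OX1]",
               "C#CC#N"],
    "note": "alkene or alkyne conjugated to an electron-withdrawing group"
  },
  {
    "alert_id": "TA617",
    "name": "phosphoric acid ester",
    "smarts": ["[PX4](=[OX1])[OX2][#6]"],
    "note": "P(=O) with at least one O-C ester linkage"
  },
  {
    "alert_id": "TA626",
    "name": "alpha,beta-unsaturated nitriles",
    "smarts": ["[CX3]=[CX3]C#N"],
    "note": "nitrile conjugated to a C=C double bond"
  },
  {
    "alert_id": "TA631",
    "name": "alpha,beta-unsaturated carboxylic acid",
    "smarts": ["[CX3]=[CX3][CX3](=[OX1])[OX2H1]"],
    "note": "carboxylic acid conjugated to a C=C double bond"
  },
  {
    "alert_id": "TA1181",
    "name": "carboxylic acid secondary amides",
    "smarts": ["[CX3](=[OX1])[NX3;H1][#6]"],
    "note": "N-monosubstituted amide"
  },
  {
    "alert_id": "TA1176",
    "name": "carboxylic acids",
    "smarts": ["[CX3](=[OX1])[OX2H1]"],
    "note": "free carboxylic acid group"
  },
  {
    "alert_id": "TA659",
    "name": "aliphatic alcohols",
    "smarts": ["[CX4][OX2H]"],
    "note": "hydroxyl on a saturated carbon"
  },
  {
    "alert_id": "TA638",
    "name": "halogenated benzylic group",
    "smarts": ["[F,Cl,Br,I][CX4][c]"],
    "note": "halogen on a benzylic carbon"
  },
  {
    "alert_id": "TA634",
    "name": "halide groups (F)",
    "smarts": ["[#6][F]"],
    "note": "fluorine on carbon"
  }
]
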