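{
  "metabolites": ["Trp", "IPYA", "ILA", "IA", "IPA", "IAM", "TA", "IAAld", "IAA", "IAld"],
  "edges": [
    {
      "substrate": "Trp",
      "product": "IPYA",
      "alternatives": [
        ["ArAT"]
      ]
    },
    {
      "substrate": "Trp",
      "product": "TA",
      "alternatives": [
        ["TDC"]
      ]
    },
    {
      "substrate": "Trp",
      "product": "IAM",
      "alternatives": [
        ["TMO"]
      ]
    },
    {
      "substrate": "IPYA",
      "product": "ILA",
      "alternatives": [
        ["fldH"],
        ["LDH"]
      ]
    },
    {
      "substrate": "ILA",
      "product": "IA",
      "alternatives": [
        ["fldA", "fldBC", "fldI"]
      ]
    },
    {
      "substrate": "IA",
      "product": "IPA",
      "alternatives": [
        ["acdA"]
      ]
    },
    {
      "substrate": "IPYA",
      "product": "IAAld",
      "alternatives": [
        ["IPD"],
        ["PPD"]
      ]
    },
    {
      "substrate": "IAAld",
      "product": "IAA",
      "alternatives": [
        ["ALD"]
      ]
    },
    {
      "substrate": "IAM",
      "product": "IAA",
      "alternatives": [
        ["amiE"]
      ]
    },
    {
      "substrate": "IAA",
      "product": "IAld",
      "alternatives": []
    }
  ]
}
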