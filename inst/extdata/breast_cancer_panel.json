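{
  "pairs": [
    {
      "disease_id": "female_breast_cancer",
      "gene_id": "ATM",
      "carrier_prevalence": 0.0019,
      "penetrance": 0.34999999999999998,
      "precision": 100,
      "test_disutility": 0
    },
    {
      "disease_id": "female_breast_cancer",
      "gene_id": "BRCA1",
      "carrier_prevalence": 0.00058,
      "penetrance": 0.72999999999999998,
      "precision": 10000,
      "test_disutility": 0
    },
    {
      "disease_id": "female_breast_cancer",
      "gene_id": "BRCA2",
      "carrier_prevalence": 0.00068000000000000005,
      "penetrance": 0.71999999999999997,
      "precision": 10000,
      "test_disutility": 0
    },
    {
      "disease_id": "female_breast_cancer",
      "gene_id": "CHEK2",
      "carrier_prevalence": 0.0025999999999999999,
      "penetrance": 0.19,
      "precision": 100,
      "test_disutility": 0
    },
    {
      "disease_id": "female_breast_cancer",
      "gene_id": "PALB2",
      "carrier_prevalence": 0.00056999999999999998,
      "penetrance": 0.38,
      "precision": 100,
      "test_disutility": 0
    }
  ]
}
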