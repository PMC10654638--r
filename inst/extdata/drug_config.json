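{
  "_comment": "Synonym lexicon and merged product labels for the two study drugs. Synonyms are the generic and trade names under which the drugs appear in spontaneous reports. The approved_indications and labeled_aes arrays are synthetic stand-ins for the merged FDA labels (all marketed specifications combined), assembled for testing; they are not the full label text.",
  "denosumab": {
    "synonyms": ["DENOSUMAB", "Prolia", "Xgeva", "Ranmark"],
    "approved_indications": [
      "osteoporosis",
      "osteoporosis postmenopausal",
      "glucocorticoid-induced osteoporosis",
      "hypercalcaemia of malignancy",
      "bone metastasis",
      "giant cell tumour of bone",
      "bone loss"
    ],
    "labeled_aes": [
      "osteonecrosis of jaw",
      "hypocalcaemia",
      "back pain",
      "bone pain",
      "tooth disorder",
      "spinal fracture",
      "pain in jaw",
      "fracture",
      "tooth extraction",
      "arthralgia",
      "nausea"
    ]
  },
  "zoledronic acid": {
    "synonyms": ["ZOLEDRONIC ACID", "ZOLEDRONATE", "Aclasta", "Reclast", "Zometa"],
    "approved_indications": [
      "osteoporosis",
      "osteoporosis postmenopausal",
      "glucocorticoid-induced osteoporosis",
      "hypercalcaemia of malignancy",
      "bone metastasis",
      "paget's disease"
    ],
    "labeled_aes": [
      "osteonecrosis",
      "osteonecrosis of jaw",
      "pain",
      "tooth extraction",
      "bone disorder",
      "pyrexia",
      "arthralgia",
      "pain in jaw",
      "hypocalcaemia",
      "nausea"
    ]
  }
}
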