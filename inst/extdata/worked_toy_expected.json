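{
  "comment": "Hand-enumerated expected results for the workedToy() knowledgebase.",
  "top_level_pathways": [1],
  "decompositions": {
    "14": {"excl": [9, 10], "incl": [9, 10]},
    "15": {"excl": [8, 9, 10], "incl": [8, 9, 10]},
    "16": {"excl": [7, 8], "incl": [7, 8, 11]}
  },
  "ancestors": {
    "1": [1],
    "2": [1, 2],
    "3": [1, 2, 3],
    "4": [1, 2, 4],
    "5": [1, 5]
  },
  "participants": {
    "1": {
      "cat0_reg0_dec0": [6, 7, 8, 12, 13, 15, 16],
      "cat0_reg0_dec1": [6, 7, 8, 9, 10, 12, 13],
      "cat1_reg1_dec0": [6, 7, 8, 12, 13, 15, 16, 18],
      "cat1_reg1_dec1": [6, 7, 8, 9, 10, 12, 13, 18]
    },
    "2": {
      "cat0_reg0_dec0": [6, 7, 8, 12, 13],
      "cat1_reg1_dec0": [6, 7, 8, 12, 13, 18],
      "cat1_reg1_dec1": [6, 7, 8, 12, 13, 18]
    }
  },
  "reaction_chains_to_15": {
    "max_length_3": [[5], [4, 5], [3, 4, 5]]
  }
}
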