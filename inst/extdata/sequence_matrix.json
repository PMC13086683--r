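{
  "comment": "Rows = sessions 1..6, columns = experimental sequences 1..7. All sequences open with two shuffling sessions; reputation sessions occur in consecutive pairs.",
  "scenarios": [
    ["shuffling", "shuffling", "shuffling", "shuffling", "shuffling", "shuffling", "shuffling"],
    ["shuffling", "shuffling", "shuffling", "shuffling", "shuffling", "shuffling", "shuffling"],
    ["voting_shuffling", "voting_shuffling", "voting_shuffling_reputation", "voting_shuffling_reputation", "voting_shuffling", "voting_shuffling", "voting_shuffling"],
    ["voting_shuffling", "voting_shuffling", "voting_shuffling_reputation", "voting_shuffling_reputation", "voting_shuffling", "voting_shuffling", "voting_shuffling"],
    ["voting_shuffling", "voting_shuffling", "voting_shuffling", "voting_shuffling", "voting_shuffling_reputation", "voting_shuffling", "voting_shuffling"],
    ["voting_shuffling", "voting_shuffling", "voting_shuffling", "voting_shuffling", "voting_shuffling_reputation", "voting_shuffling", "voting_shuffling"]
  ]
}
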