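{
  "comment": [
    "Default AZFc definition set: six amplicon classes named by colors, two",
    "inverted-repeat (IR) classes quantified identically, one single-copy",
    "X-degenerate control region. Interval coordinates in the companion BED",
    "are an approximate one-time transcription of the published AZFc",
    "architecture onto GRCh38 chrY; this file is configuration, not code.",
    "The gr/gr deletion signature removes six amplicon copies (blue -1,",
    "green -1, red -2, gray -1, yellow -1) and leaves IR dosage unchanged;",
    "the three known gr/gr breakpoint subtypes are copy-number-identical and",
    "therefore indistinguishable here."
  ],
  "classes": {
    "ctrl": { "reference_copies": 1, "is_control": true },
    "blue": { "reference_copies": 4, "is_control": false },
    "teal": { "reference_copies": 2, "is_control": false },
    "green": { "reference_copies": 3, "is_control": false },
    "red": { "reference_copies": 4, "is_control": false },
    "gray": { "reference_copies": 2, "is_control": false },
    "yellow": { "reference_copies": 2, "is_control": false },
    "ir1": { "reference_copies": 2, "is_control": false },
    "ir2": { "reference_copies": 2, "is_control": false }
  },
  "signatures": [
    {
      "name": "REFERENCE",
      "category": "REFERENCE",
      "copy_vector": { "blue": 4, "teal": 2, "green": 3, "red": 4,
                       "gray": 2, "yellow": 2, "ir1": 2, "ir2": 2 }
    },
    {
      "name": "GRGR_DEL",
      "category": "GRGR_DEL",
      "copy_vector": { "blue": 3, "teal": 2, "green": 2, "red": 2,
                       "gray": 1, "yellow": 1, "ir1": 2, "ir2": 2 }
    },
    {
      "name": "GRGR_DUP",
      "category": "OTHER_CNV",
      "copy_vector": { "blue": 5, "teal": 2, "green": 4, "red": 6,
                       "gray": 3, "yellow": 3, "ir1": 2, "ir2": 2 }
    },
    {
      "name": "B2B4_DEL",
      "category": "OTHER_CNV",
      "copy_vector": { "blue": 2, "teal": 2, "green": 0, "red": 0,
                       "gray": 0, "yellow": 0, "ir1": 1, "ir2": 1 }
    }
  ]
}
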