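[
  {
    "age_low": 7,
    "age_high": 8,
    "sex": "male",
    "ear": 65,
    "ul": 300
  },
  {
    "age_low": 9,
    "age_high": 13,
    "sex": "male",
    "ear": 73,
    "ul": 450
  },
  {
    "age_low": 14,
    "age_high": 18,
    "sex": "male",
    "ear": 95,
    "ul": 500
  },
  {
    "age_low": 19,
    "age_high": 69,
    "sex": "male",
    "ear": 95,
    "ul": 600
  },
  {
    "age_low": 7,
    "age_high": 8,
    "sex": "female",
    "ear": 65,
    "ul": 300
  },
  {
    "age_low": 9,
    "age_high": 13,
    "sex": "female",
    "ear": 73,
    "ul": 450
  },
  {
    "age_low": 14,
    "age_high": 18,
    "sex": "female",
    "ear": 95,
    "ul": 500
  },
  {
    "age_low": 19,
    "age_high": 69,
    "sex": "female",
    "ear": 95,
    "ul": 600
  }
]
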