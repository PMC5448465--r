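{
  "manufacturer": {
    "bread": {
      "market_share": 0.95,
      "iodine_conc": 58,
      "salt_fraction": 1
    },
    "pizza": {
      "market_share": 0.4,
      "iodine_conc": 20,
      "salt_fraction": 0.5
    },
    "meat_products": {
      "market_share": 0.005,
      "iodine_conc": 20,
      "salt_fraction": 1
    }
  },
  "discretionary": {
    "iodine_conc": 20,
    "added_amount": {
      "fish": 0.7,
      "eggs": 0.7,
      "vegetables": 0.7,
      "potatoes": 0.7
    },
    "use_share": {
      "fish": 0.5,
      "eggs": 0.5,
      "vegetables": 0.5,
      "potatoes": 0.5
    }
  },
  "never_user_proportions": [
    {
      "age_low": 7,
      "age_high": 8,
      "sex": "male",
      "proportion": 0.45
    },
    {
      "age_low": 9,
      "age_high": 13,
      "sex": "male",
      "proportion": 0.4
    },
    {
      "age_low": 14,
      "age_high": 18,
      "sex": "male",
      "proportion": 0.35
    },
    {
      "age_low": 19,
      "age_high": 30,
      "sex": "male",
      "proportion": 0.25
    },
    {
      "age_low": 31,
      "age_high": 50,
      "sex": "male",
      "proportion": 0.3
    },
    {
      "age_low": 51,
      "age_high": 69,
      "sex": "male",
      "proportion": 0.35
    },
    {
      "age_low": 7,
      "age_high": 8,
      "sex": "female",
      "proportion": 0.45
    },
    {
      "age_low": 9,
      "age_high": 13,
      "sex": "female",
      "proportion": 0.4
    },
    {
      "age_low": 14,
      "age_high": 18,
      "sex": "female",
      "proportion": 0.35
    },
    {
      "age_low": 19,
      "age_high": 30,
      "sex": "female",
      "proportion": 0.25
    },
    {
      "age_low": 31,
      "age_high": 50,
      "sex": "female",
      "proportion": 0.3
    },
    {
      "age_low": 51,
      "age_high": 69,
      "sex": "female",
      "proportion": 0.35
    }
  ]
}
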