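{
  "name": "table1",
  "experiments": [
    {
      "tag": "phe",
      "tracer": "phe",
      "fraction": 0.35,
      "baseline": 0
    },
    {
      "tag": "tyr",
      "tracer": "tyr",
      "fraction": 0.35,
      "baseline": 0
    }
  ],
  "targets": [
    {
      "name": "H_frac",
      "value": 4,
      "tol": 2,
      "mode": "absolute"
    },
    {
      "name": "G_frac",
      "value": 45,
      "tol": 2,
      "mode": "absolute"
    },
    {
      "name": "S_frac",
      "value": 51,
      "tol": 2,
      "mode": "absolute"
    },
    {
      "name": "SG_ratio",
      "value": 1.09,
      "tol": 0.1,
      "mode": "relative"
    },
    {
      "name": "G",
      "value": 22.3,
      "tol": 5,
      "mode": "absolute",
      "experiment": "phe"
    },
    {
      "name": "S",
      "value": 21,
      "tol": 5,
      "mode": "absolute",
      "experiment": "phe"
    },
    {
      "name": "total_lignin",
      "value": 22.2,
      "tol": 5,
      "mode": "absolute",
      "experiment": "phe"
    },
    {
      "name": "wall_coumaric",
      "value": 21,
      "tol": 5,
      "mode": "absolute",
      "experiment": "phe"
    },
    {
      "name": "wall_ferulic",
      "value": 23,
      "tol": 5,
      "mode": "absolute",
      "experiment": "phe"
    },
    {
      "name": "G",
      "value": 16.5,
      "tol": 5,
      "mode": "absolute",
      "experiment": "tyr"
    },
    {
      "name": "S",
      "value": 18.1,
      "tol": 5,
      "mode": "absolute",
      "experiment": "tyr"
    },
    {
      "name": "total_lignin",
      "value": 18.6,
      "tol": 5,
      "mode": "absolute",
      "experiment": "tyr"
    },
    {
      "name": "wall_coumaric",
      "value": 17,
      "tol": 5,
      "mode": "absolute",
      "experiment": "tyr"
    },
    {
      "name": "wall_ferulic",
      "value": 13,
      "tol": 5,
      "mode": "absolute",
      "experiment": "tyr"
    }
  ]
}
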