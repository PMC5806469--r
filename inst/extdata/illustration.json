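{
  "name": "illustration",
  "r": 1,
  "metabolites": [
    {
      "id": "X1",
      "name": "X1",
      "compartment": "cytosol",
      "species": "x1"
    },
    {
      "id": "X2",
      "name": "X2",
      "compartment": "cytosol",
      "species": "x24"
    },
    {
      "id": "X3",
      "name": "X3",
      "compartment": "cytosol",
      "species": "x3"
    },
    {
      "id": "X4",
      "name": "X4",
      "compartment": "ER",
      "species": "x24"
    }
  ],
  "fluxes": [
    {
      "id": "Vin1",
      "kind": "input",
      "products": [
        {
          "metabolite": "X1",
          "coefficient": 1
        }
      ],
      "tracer": "in1"
    },
    {
      "id": "Vin2",
      "kind": "input",
      "products": [
        {
          "metabolite": "X3",
          "coefficient": 1
        }
      ],
      "tracer": "in2"
    },
    {
      "id": "V1",
      "kind": "enzymatic",
      "substrates": [
        {
          "metabolite": "X1",
          "coefficient": -1
        }
      ],
      "products": [
        {
          "metabolite": "X2",
          "coefficient": 1
        }
      ]
    },
    {
      "id": "V2",
      "kind": "efflux",
      "substrates": [
        {
          "metabolite": "X2",
          "coefficient": -1
        }
      ]
    },
    {
      "id": "V3",
      "kind": "enzymatic",
      "substrates": [
        {
          "metabolite": "X3",
          "coefficient": -1
        }
      ],
      "products": [
        {
          "metabolite": "X4",
          "coefficient": 1
        }
      ]
    },
    {
      "id": "D",
      "kind": "diffusion_net",
      "substrates": [
        {
          "metabolite": "X2",
          "coefficient": -1
        }
      ],
      "products": [
        {
          "metabolite": "X4",
          "coefficient": 1
        }
      ]
    },
    {
      "id": "V4",
      "kind": "efflux",
      "substrates": [
        {
          "metabolite": "X4",
          "coefficient": -1
        }
      ]
    },
    {
      "id": "V5",
      "kind": "efflux",
      "substrates": [
        {
          "metabolite": "X4",
          "coefficient": -1
        }
      ]
    }
  ]
}
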