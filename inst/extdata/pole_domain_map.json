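{
  "protein_length": 2286,
  "intervals": [
    {
      "name": "NTL",
      "start": 1,
      "end": 1183,
      "tier": "lobe"
    },
    {
      "name": "CTL",
      "start": 1184,
      "end": 2286,
      "tier": "lobe"
    },
    {
      "name": "N-terminal",
      "start": 1,
      "end": 267,
      "tier": "domain"
    },
    {
      "name": "ExoD",
      "start": 268,
      "end": 471,
      "tier": "domain"
    },
    {
      "name": "Polymerase",
      "start": 472,
      "end": 1183,
      "tier": "domain"
    },
    {
      "name": "Linker",
      "start": 1184,
      "end": 1308,
      "tier": "domain"
    },
    {
      "name": "CTD",
      "start": 1309,
      "end": 2286,
      "tier": "domain"
    },
    {
      "name": "Palm",
      "start": 612,
      "end": 910,
      "tier": "subdomain"
    },
    {
      "name": "Fingers",
      "start": 911,
      "end": 1040,
      "tier": "subdomain"
    },
    {
      "name": "Thumb",
      "start": 1041,
      "end": 1183,
      "tier": "subdomain"
    }
  ]
}
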