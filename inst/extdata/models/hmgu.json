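{
  "name": "HMGU",
  "note": "Synthetic reconstruction of the HMGU zirconium model wiring: 10 compartments, 12 first-order transfers (shared indices 1-8, model-specific 9-12). The two bone pools of the ICRP structure are combined into a single bone compartment; direct bone-to-excreta transfers are replaced by exchange with plasma and a plasma-to-gut route. Exact original wiring is not deposited; this reconstruction satisfies the documented structural constraints (in particular y5 inflows are exactly x8 from y10 and x10 from y1).",
  "compartments": ["y1", "y2", "y3", "y4", "y5", "y6", "y7", "y8", "y9", "y10"],
  "compartment_names": {
    "y1": "plasma (transfer compartment)",
    "y2": "bone",
    "y3": "other soft tissue",
    "y4": "urinary bladder contents",
    "y5": "upper large intestine contents",
    "y6": "lower large intestine contents",
    "y7": "urine",
    "y8": "feces",
    "y9": "stomach contents",
    "y10": "small intestine contents"
  },
  "transfers": [
    {"rate": 1,  "source": "y9",  "target": "y10"},
    {"rate": 2,  "source": "y5",  "target": "y6"},
    {"rate": 3,  "source": "y6",  "target": "y8"},
    {"rate": 4,  "source": "y4",  "target": "y7"},
    {"rate": 5,  "source": "y1",  "target": "y4"},
    {"rate": 6,  "source": "y1",  "target": "y3"},
    {"rate": 7,  "source": "y10", "target": "y1"},
    {"rate": 8,  "source": "y10", "target": "y5"},
    {"rate": 9,  "source": "y1",  "target": "y2"},
    {"rate": 10, "source": "y1",  "target": "y5"},
    {"rate": 11, "source": "y2",  "target": "y1"},
    {"rate": 12, "source": "y3",  "target": "y1"}
  ],
  "entry": "y9",
  "terminals": ["y7", "y8"],
  "plasma": "y1",
  "bones": ["y2"]
}
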