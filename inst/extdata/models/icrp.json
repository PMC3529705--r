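{
  "name": "ICRP",
  "note": "Synthetic reconstruction of the ICRP systemic+GI zirconium model wiring: 11 compartments, 15 first-order transfers (shared indices 1-8, model-specific 13-19). Compartment roles follow the published structure; the exact transfer list of the original is not deposited, so this wiring satisfies the documented structural constraints and is flagged as a reconstruction.",
  "compartments": ["y1", "y2", "y3", "y4", "y5", "y6", "y7", "y8", "y9", "y10", "y11"],
  "compartment_names": {
    "y1": "plasma (transfer compartment)",
    "y2": "trabecular bone surface",
    "y3": "cortical bone surface",
    "y4": "other soft tissue",
    "y5": "upper large intestine contents",
    "y6": "lower large intestine contents",
    "y7": "urine",
    "y8": "feces",
    "y9": "stomach contents",
    "y10": "small intestine contents",
    "y11": "urinary bladder contents"
  },
  "transfers": [
    {"rate": 1,  "source": "y9",  "target": "y10"},
    {"rate": 2,  "source": "y5",  "target": "y6"},
    {"rate": 3,  "source": "y6",  "target": "y8"},
    {"rate": 4,  "source": "y11", "target": "y7"},
    {"rate": 5,  "source": "y1",  "target": "y11"},
    {"rate": 6,  "source": "y1",  "target": "y4"},
    {"rate": 7,  "source": "y10", "target": "y1"},
    {"rate": 8,  "source": "y10", "target": "y5"},
    {"rate": 13, "source": "y1",  "target": "y2"},
    {"rate": 14, "source": "y1",  "target": "y3"},
    {"rate": 15, "source": "y2",  "target": "y11"},
    {"rate": 16, "source": "y2",  "target": "y5"},
    {"rate": 17, "source": "y3",  "target": "y11"},
    {"rate": 18, "source": "y3",  "target": "y5"},
    {"rate": 19, "source": "y4",  "target": "y1"}
  ],
  "entry": "y9",
  "terminals": ["y7", "y8"],
  "plasma": "y1",
  "bones": ["y2", "y3"]
}
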