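{
  "comment": "Package-assembled metadata for the bundled cCA key: relatives per target species follow the published identification narrative and the phylogenetic studies it cites; not itself a published table.",
  "relatives": {
    "Carcharodon carcharias": ["Isurus oxyrinchus", "Isurus paucus", "Lamna nasus", "Lamna ditropis"],
    "Carcharhinus longimanus": ["Carcharhinus obscurus", "Carcharhinus galapagensis", "Carcharhinus perezi"],
    "Cetorhinus maximus": ["Carcharodon carcharias", "Lamna nasus", "Isurus oxyrinchus"],
    "Lamna nasus": ["Lamna ditropis", "Isurus oxyrinchus", "Carcharodon carcharias"],
    "Rhincodon typus": ["Ginglymostoma cirratum"],
    "Sphyrna lewini": ["Sphyrna mokarran", "Sphyrna zygaena", "Sphyrna tudes", "Sphyrna tiburo"],
    "Sphyrna mokarran": ["Sphyrna lewini", "Sphyrna zygaena", "Sphyrna tudes", "Sphyrna tiburo"],
    "Sphyrna zygaena": ["Sphyrna lewini", "Sphyrna mokarran", "Sphyrna tudes", "Sphyrna tiburo"]
  },
  "low_confidence_positions": [60]
}
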