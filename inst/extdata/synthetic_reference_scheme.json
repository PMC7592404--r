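{"n_levels":16,"edges":[-11.9876901114264,40.784253028714,93.5561961688545,146.328139308995,199.100082449135,251.872025589276,304.643968729416,357.415911869557,410.187855009697,462.959798149838,515.731741289978,568.503684430118,621.275627570259,674.047570710399,726.81951385054,779.59145699068,832.363400130821],"provenance":"synthetic_phantom_seed42"}
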