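>metazoa_A
NPDKVEIGGGTAAFAAYREL
>metazoa_B
NPDKVDIGGGTAAFAAYREL
>bacteria_A
MKHYDVLGAGYGGIVAAREL
>bacteria_B
MKHYDVLGAGYGGIVAARDL
>fungi_A
QSTWLELGSGWGAISAWKEL
>fungi_B
QSTWLELGSGWGAISAWKEL
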