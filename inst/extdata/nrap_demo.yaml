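# Miniature Nrap-like worked example: a 45-exon gene whose cassette exons
# (2, 12, 17, 37-40) distinguish three annotated isoforms; per-sample FL
# totals mirror the published figure. Build with:
#   psiphase simulate --scenario nrap_demo.yaml --out-dir fixture --seed 1
name: nrap_demo
size_window: [5000, 10000]
genes:
  NrapD:
    chrom: chrS
    strand: '+'
    exons:
      - [1000, 1120]
      - [1320, 1440]
      - [1640, 1760]
      - [1960, 2080]
      - [2280, 2400]
      - [2600, 2720]
      - [2920, 3040]
      - [3240, 3360]
      - [3560, 3680]
      - [3880, 4000]
      - [4200, 4320]
      - [4520, 4640]
      - [4840, 4960]
      - [5160, 5280]
      - [5480, 5600]
      - [5800, 5920]
      - [6120, 6240]
      - [6440, 6560]
      - [6760, 6880]
      - [7080, 7200]
      - [7400, 7520]
      - [7720, 7840]
      - [8040, 8160]
      - [8360, 8480]
      - [8680, 8800]
      - [9000, 9120]
      - [9320, 9440]
      - [9640, 9760]
      - [9960, 10080]
      - [10280, 10400]
      - [10600, 10720]
      - [10920, 11040]
      - [11240, 11360]
      - [11560, 11680]
      - [11880, 12000]
      - [12200, 12320]
      - [12520, 12640]
      - [12840, 12960]
      - [13160, 13280]
      - [13480, 13600]
      - [13800, 13920]
      - [14120, 14240]
      - [14440, 14560]
      - [14760, 14880]
      - [15080, 15200]
    transcripts:
      NRAP_FULL: all
      NRAP_NO12: {exclude: [12]}
      NRAP_NO2_12: {exclude: [2, 12]}
samples:
  heart:
    - {gene: NrapD, transcript: NRAP_NO12, consensus: 30, fl_total: 541}
    - {gene: NrapD, transcript: NRAP_NO2_12, consensus: 3, fl_total: 14}
  soleus:
    - {gene: NrapD, transcript: NRAP_NO12, consensus: 60, fl_total: 2177}
    - {gene: NrapD, transcript: NRAP_NO2_12, consensus: 5, fl_total: 26}
    - {gene: NrapD, transcript: NRAP_FULL, consensus: 20, fl_total: 341}
  edl:
    - {gene: NrapD, transcript: NRAP_FULL, consensus: 35, fl_total: 557}
    - {gene: NrapD, transcript: NRAP_NO12, consensus: 20, fl_total: 280}
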