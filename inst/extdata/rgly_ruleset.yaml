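# Presence rules for the reductive glycine pathway screen.
#
# A complex is present when one co-occurrence cluster (hits chained at gaps
# <= window_bp) contains hits to at least min_detected DISTINCT genes of the
# complex. Single genes are counted genome-wide. The pathway is present when
# an FDH complex (any of the four; skipped in fdh_optional mode), the GCS,
# the formate-THF ligase and the methenyl-THF cyclohydrolase are present
# together with route A (glycine reductase + PTA or ACK) and/or route B
# (SHMT + serine deaminase).
#
# Gene id lists for the non-native FDH complexes name the loci of the
# reference operons used as queries; min_detected values are the operative
# thresholds.

window_bp: 20000
min_identity: 25.0
max_evalue: 1.0e-4

complexes:
  GCS:
    genes: [DsvG11_0325, DsvG11_0326, DsvG11_0327, DsvG11_0328]
    min_detected: 3
    requires_cooccurrence: true
  GR:
    # 7 components: A, B-alpha, B-beta, C-alpha, C-beta, thioredoxin,
    # thioredoxin reductase; the two thioredoxin genes (or any other two)
    # may sit elsewhere in the genome.
    genes: [DsvG11_1441, DsvG11_1442, DsvG11_1443, DsvG11_1444, DsvG11_1445,
            DsvG11_1446, DsvG11_1447]
    min_detected: 5
    requires_cooccurrence: true
  FDH_1.17.2.3:
    genes: [DsvG11_0564, DsvG11_0565, DsvG11_0566, DsvG11_0567, DsvG11_0568,
            DsvG11_0569]
    min_detected: 4
    requires_cooccurrence: true
  FDH_1.17.1.9:
    genes: [METTRDRAFT_RS0208105, METTRDRAFT_RS0208110, METTRDRAFT_RS0208115,
            METTRDRAFT_RS0208120, METTRDRAFT_RS0208125]
    min_detected: 4
    requires_cooccurrence: true
  FDH_1.17.1.11:
    genes: [Curi_c29330, Curi_c29340, Curi_c29350, Curi_c29360, Curi_c29370,
            Curi_c29380, Curi_c29390, Curi_c29400]
    min_detected: 5
    requires_cooccurrence: true
  FDH_1.17.5.3:
    genes: [b1474, b1475, b1476]
    min_detected: 3
    requires_cooccurrence: true

singles:
  FTL: DsvG11_3068
  MTCD: DsvG11_1518
  PTA: DsvG11_0941
  ACK: DsvG11_0942
  SHMT: DsvG11_2276
  SDA: DsvG11_1577

pathway:
  required_singles: [FTL, MTCD]
  fdh_complexes: [FDH_1.17.2.3, FDH_1.17.1.9, FDH_1.17.1.11, FDH_1.17.5.3]
  gcs: GCS
  route_A:
    complex: GR
    any_of_singles: [PTA, ACK]
  route_B:
    singles: [SHMT, SDA]
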