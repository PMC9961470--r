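# Bundled data

- `b10v3_fish_evidence.tsv` — published per-track chromosome assignments
  (markers, reference-guided scaffolding against the 9930 and Gy14
  genomes, proteome BLASTP, DArT-seq, BAC/FISH) for the six FISH-detected
  contigs of the cucumber B10v3 genome, in long format. Scaffolding
  labels keep their reference suffix (e.g. `Chr2_9930`) exactly as
  reported; [read_evidence_tsv()] normalizes them.
- `b10v3_stc_probes.tsv` — the published STC probe table: each BAC-derived
  STC probe, the B10v3 contig it maps to by BLASTN, the reported
  bioinformatics consensus chromosome and the chromosome from the BAC/FISH
  analysis.
- `b10v3_evidence_synthetic_fill.tsv` — SYNTHETIC stand-in rows for
  ctg775 and ctg1000, whose per-track assignments were not published
  individually; every bioinformatic track is set to the contig's reported
  consensus chromosome (all published sources for these contigs agree).
  Used only to complete the twelve-probe consensus cross-check.
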