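# Expected default-threshold filter verdicts for toy_mutmap.vcf
# (one-bulk design), derived by evaluating each rule by hand:
#   minMQ = 40; per-bulk depth in [8, 250]; strand-bias Phred cutoff 40;
#   indels excluded; parent must be homozygous and non-missing.
# pos 1000: MQ 60, parent 0/0 depth 20, bulk depth 20, SNP, balanced
#           strands (Fisher p = 1, Phred 0) -> keep.
# pos 2000: parent GT ./., parent depth 0 -> MISSING_PARENT.
# pos 3000: parent 0/1 carries both alleles -> PARENT_HET.
# pos 4000: two alternate alleles -> MULTIALLELIC.
# pos 5000: ALT allele "AT" is length 2 -> INDEL.
# pos 6000: MQ 20 < 40 -> LOW_MQ.
# pos 7000: bulk strands ADF=(20,0), ADR=(0,20); two-sided Fisher exact
#           p = 2/choose(40,20) = 1.4509e-11, Phred = 108.38 > 40
#           -> STRAND_BIAS.
# pos 8000: bulk depth 4 < 8 -> LOW_DEPTH.
# pos 9000: bulk depth 300 > 250 -> HIGH_DEPTH.
# pos 10000: MQ 60, parent hom ref, bulk depth 18, SNP-index 1.0 -> keep.
# Kept count under defaults: 2.
CHROM	POS	KEEP	REASONS
chr1	1000	TRUE	.
chr1	2000	FALSE	MISSING_PARENT
chr1	3000	FALSE	PARENT_HET
chr1	4000	FALSE	MULTIALLELIC
chr1	5000	FALSE	INDEL
chr1	6000	FALSE	LOW_MQ
chr1	7000	FALSE	STRAND_BIAS
chr1	8000	FALSE	LOW_DEPTH
chr1	9000	FALSE	HIGH_DEPTH
chr1	10000	TRUE	.
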