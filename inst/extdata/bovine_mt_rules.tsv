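# Default taurine mtDNA haplogroup rule set (editable; synthetic defaults).
# Positions are 1-based on the circular bovine reference V00654 (16338 bp).
# The T/Q split at 15953 follows the primary literature; the remaining
# site=allele pairs are illustrative placeholders chosen for internal
# consistency and should be replaced with curated diagnostic positions
# (e.g. from whole-mitogenome surveys) before use on real data.
# sites: comma-separated position=base; "." for none; parent "." = root.
label	parent	sites
T	.	15953=G
Q	.	15953=A
P	.	16016=T
R	.	16074=A
T1	T	16050=T
T1f	T1	16113=C
T2	T	16185=T
T3	T	.
T3b	T3	16057=G
T4	T3	16042=C
T5	T	13010=A
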