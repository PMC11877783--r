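Synthetic ten-patient cohort fixture.

These tables are NOT patient data: the underlying study deposited no
sequencing data, so the per-patient mutation-sharing relations reported
in its text were transcribed here with synthetic read counts at
panel-like depths (~1000x). Counts were chosen so that default
presence-calling parameters reproduce the stated sharing pattern;
coordinates are approximate, allele-level identities (e.g. the two
distinct PTEN and SPTA1 mutations of GBM-1250) are preserved.
Several patients also carry a heterozygous germline variant to
exercise blood-based somatic filtering.
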