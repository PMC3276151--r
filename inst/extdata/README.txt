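candidates_synthetic.csv

Synthetic stand-in positions for the 22 candidate genes (sex-biased
expression in the developing genital disc) used by the candidate-locus
resampling test.  The gene names are real; the published analysis does
not print their map coordinates, so the cM positions here are plausible
standard-map placements constructed for this package's synthetic
pipeline, not curated FlyBase coordinates.  Positions are cM on the
package's reference chromosome axes (X 0-66, chr2 0-108 with the
centromere at 55, chr3 0-111 with the centromere at 47); 18 of the 22
genes are autosomal, matching the count used by the test.
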