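# Shared fixtures: random protein strings over the 20 standard residues and
# the two scoring schemes exercised throughout (BLOSUM62 affine 10/2, and
# the +3/-1 match/mismatch table with linear gap penalty 1).

blosum <- scoring_scheme()
mm31 <- scoring_scheme(match_mismatch_matrix(3L, -1L), 1L, 1L)

rand_protein <- function(len) {
  paste(sample(aa_alphabet()[1:20], len, replace = TRUE), collapse = "")
}

rand_pair <- function(max_len = 200L) {
  list(q = rand_protein(sample.int(max_len, 1L)),
       s = rand_protein(sample.int(max_len, 1L)))
}
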