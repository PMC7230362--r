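# Shared fixtures: the bundled synthetic references wired into templates, and
# small constructors used across test files.

fix_panel <- toy_index_panel(2)
fix_primers <- toy_primers()
fix_inserts <- toy_inserts()

fix_template <- function(insert = fix_inserts$bases[1], pair = 1,
                         name = "spA", sample_label = fix_panel$sample_label[pair]) {
  amplicon_template(insert,
                    fix_primers$bases[1], fix_primers$bases[2],
                    fix_panel$forward_index[pair], fix_panel$reverse_index[pair],
                    name = name, sample_label = sample_label)
}

fix_template_b <- function(pair = 1) {
  fix_template(insert = fix_inserts$bases[2], pair = pair, name = "spB")
}

# uniform-quality read set from plain sequences
fix_reads <- function(bases, q = 12, ids = sprintf("r%03d", seq_along(bases))) {
  read_set(ids, bases, vapply(nchar(bases), function(n)
    strrep(intToUtf8(q + 33L), n), character(1)))
}

# plant exactly n_sub substitutions at given positions of a sequence
mutate_subs <- function(bases, pos) {
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  ch[pos] <- rot[ch[pos]]
  paste(ch, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
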