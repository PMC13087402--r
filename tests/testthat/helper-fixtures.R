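# shared helpers for building small random fixtures in code

random_descriptor_table <- function(n, p, seed) {
  set.seed(seed)
  descriptor_table(matrix(rnorm(n * p), n, p),
                   compound_ids = sprintf("cmp%02d", seq_len(n)),
                   descriptor_names = sprintf("d%02d", seq_len(p)))
}

panel_activity <- function() read_activity_table(qsarpipe_example("activity"))

panel_tree_descriptors <- function() {
  read_descriptor_table(qsarpipe_example("tree_descriptors"))
}
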