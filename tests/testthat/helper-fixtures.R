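# Shared tiny fixtures; everything is generated in code at test time.

tiny_cfg <- function(layers = 2L, d = 16L, heads = 2L, ffw = 24L,
                     window = 4L) {
  student_config(num_layers = layers, hidden_dim = d, num_heads = heads,
                 feedforward_dim = ffw, dropout = 0, rel_window = window)
}

random_records <- function(n, len_range = c(10L, 30L), seed = 1L) {
  set.seed(seed)
  letters20 <- aa_vocabulary()$tokens[1:20]
  tibble::tibble(
    id = sprintf("r%03d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) {
      len <- if (len_range[1] == len_range[2]) len_range[1] else
        sample(len_range[1]:len_range[2], 1)
      paste(sample(letters20, len, replace = TRUE), collapse = "")
    }, ""))
}

random_simplex <- function(n, V) {
  m <- matrix(stats::rexp(n * V), n, V)
  m / rowSums(m)
}

new_store_dir <- function() {
  file.path(tempfile("store"), "ts")
}
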