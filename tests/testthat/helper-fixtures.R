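# Fixture builders used across test files. All fixtures are generated in
# code at test time.

# A scaled-down generator configuration for tests about mechanics rather
# than power: same design, lower cell intensities.
small_config <- function(seed = 1L, ...) {
  generator_config(seed = seed,
                   intensity = c(CA1 = 300, CA2 = 300, CA3 = 300,
                                 DG = 450, EC = 250),
                   ...)
}

# Configuration matched to the restored-gene recovery analysis: about 800
# EC excitatory cells per group (3 samples x EC area x intensity x
# excitatory share), designed effect x2.5 on the 12 restored genes.
restored_config <- function(seed) {
  generator_config(seed = seed,
                   intensity = c(CA1 = 150, CA2 = 150, CA3 = 150,
                                 DG = 250, EC = 230))
}

# Build a cell_matrix directly from a dense counts matrix.
dense_cell_matrix <- function(counts, in_sgl = NULL, group = NULL,
                              region = NULL, x = NULL, y = NULL,
                              sample_id = "s1") {
  n <- ncol(counts)
  colnames(counts) <- as.character(seq_len(n))
  cells <- tibble::tibble(
    cell_id = colnames(counts),
    x = x %||% runif(n, 0, 1000), y = y %||% runif(n, 0, 1000),
    sample_id = sample_id,
    group = group %||% "C-NB",
    region = region %||% "DG",
    in_sgl = in_sgl %||% FALSE
  )
  cell_matrix(counts, cells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random simple (star-shaped) polygon around a centre.
random_polygon <- function(n_vertices = 7, centre = c(0, 0), radius = 1) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, 0.3 * radius, radius)
  cbind(centre[1] + r * cos(ang), centre[2] + r * sin(ang))
}

unit_square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
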