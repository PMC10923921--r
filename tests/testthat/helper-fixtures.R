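# Small in-code fixtures shared across test files.

# Write a long-format RT CSV and return its path.
write_rt_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# A tiny rt_table: `n_mol` molecules measured in each method of `cms`,
# rt in method j = warp_j(u) for a per-method affine warp (monotone, exact).
tiny_table <- function(n_mol = 12, cms = c("CMA", "CMB", "CMC"),
                       slopes = NULL, offsets = NULL) {
  u <- seq(0.05, 0.95, length.out = n_mol)
  if (is.null(slopes)) slopes <- seq(8, 12, length.out = length(cms))
  if (is.null(offsets)) offsets <- seq(0.5, 1.5, length.out = length(cms))
  rows <- do.call(rbind, lapply(seq_along(cms), function(j) {
    data.frame(molecule_id = sprintf("M%02d", seq_len(n_mol)),
               cm_id = cms[j], rt = offsets[j] + slopes[j] * u)
  }))
  rt_table(rows)
}

# Example method metadata JSON (one 10-minute method, 7 breakpoints).
example_cm_json <- function(path = tempfile(fileext = ".json")) {
  writeLines('[{
    "cm_id": "CM01",
    "column": "HSS T3 100x2.1mm 1.8um",
    "mobile_phase_a": "90% H2O + 10% MeOH + 0.01% FA + 5 mM NH4COOH",
    "mobile_phase_b": "MeOH + 0.01% FA + 5 mM NH4COOH",
    "additive_family": "A1B1",
    "gradient": [[0, 0.2, 5], [1, 0.2, 5], [2, 0.2, 40], [6, 0.2, 100],
                 [8, 0.2, 100], [8.1, 0.2, 5], [10, 0.2, 5]],
    "run_time": 10,
    "temperature": 30
  }]', path)
  path
}

# A behavior_som object built by hand (for selection tests that need full
# control over group memberships).
manual_som <- function(assignment, prototypes, grid) {
  structure(list(assignment = assignment, prototypes = prototypes,
                 grid = grid, n_groups = nrow(prototypes),
                 epochs = 0L, seed = 0L),
            class = "behavior_som")
}
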