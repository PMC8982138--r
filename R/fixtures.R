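# Tiny deterministic fixtures shipped as plain delimited text, with
# hand-computed expected values for the worked examples. These separate
# the reproducible test surface from the stochastic simulator.

fixture_names <- c("tiny_2x3", "single_taxon", "zero_heavy")

#' Load a named fixture
#'
#' Fixtures are small hand-sized datasets stored as CSV under
#' `extdata/fixtures`, each with a JSON metadata file recording expected
#' values of package operations (with the arithmetic provenance of each).
#'
#' Available fixtures: `"tiny_2x3"` (2 samples, 3 taxa, 2 observed; the
#' worked scaling-factor numbers), `"single_taxon"` (1 sample, 1 taxon;
#' count-only), `"zero_heavy"` (mostly zero counts).
#'
#' @param name Fixture name.
#' @return A list of class `fixture`: `name`, `counts`, `conc` (`NULL` for
#'   count-only fixtures), `paired` (`NULL` when unpaired), and `expected`
#'   (named list from the metadata).
#' @export
load_fixture <- function(name) {
  if (!name %in% fixture_names) {
    stop("unknown fixture '", name, "'; available: ",
         paste(fixture_names, collapse = ", "), call. = FALSE)
  }
  dir <- system.file("extdata", "fixtures", package = "microconc",
                     mustWork = TRUE)
  counts <- read_count_table(file.path(dir, paste0(name, "_W.csv")))
  v_path <- file.path(dir, paste0(name, "_V.csv"))
  conc <- if (file.exists(v_path)) read_concentration_table(v_path) else NULL
  meta <- jsonlite::read_json(file.path(dir, paste0(name, "_meta.json")),
                              simplifyVector = TRUE)
  paired <- if (!is.null(conc)) align_tables(counts, conc) else NULL
  structure(
    list(name = name, counts = counts, conc = conc, paired = paired,
         expected = meta$expected, provenance = meta$provenance),
    class = "fixture"
  )
}
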