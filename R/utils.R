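`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded operations inside
#' the package do not disturb the caller's random number stream.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

.espviscCache <- new.env(parent = emptyenv())

readTable <- function(name) {
  key <- paste0("tbl_", name)
  if (!is.null(.espviscCache[[key]])) return(.espviscCache[[key]])
  path <- system.file("extdata", paste0(name, ".csv"), package = "espvisc")
  if (path == "") path <- file.path("inst", "extdata", paste0(name, ".csv"))
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  .espviscCache[[key]] <- tbl
  tbl
}

elementMasses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974)

standardResidues <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                      "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                      "THR", "TRP", "TYR", "VAL")
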