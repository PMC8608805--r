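# internal helpers

.sd_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom utils head tail
NULL

.stop <- function(..., class = "stardiplo_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.assertGene <- function(gene) {
  if (!is.character(gene) || length(gene) != 1L ||
      !gene %in% c("CYP2D6", "CYP2C19"))
    .stop("'gene' must be \"CYP2D6\" or \"CYP2C19\"")
  gene
}

# run expr with a fixed seed, restoring the caller's RNG state afterwards
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "stardiplo")
  if (!nzchar(path)) .stop("built-in data file not found: ", file)
  path
}
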