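#' @import methods
#' @importFrom stats rnorm runif pnorm dnorm setNames
#' @importFrom utils packageVersion modifyList
#' @importFrom tools md5sum file_ext file_path_sans_ext
#' @importFrom igraph make_graph components
#' @importFrom EBImage makeBrush opening erode
#' @importFrom png readPNG writePNG
#' @importFrom tiff readTIFF writeTIFF
#' @importFrom jsonlite write_json toJSON read_json
#' @importFrom yaml read_yaml
#' @importFrom optparse OptionParser make_option parse_args
NULL

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a 31-bit sub-seed from a base seed and an index, so that each
# phantom / epoch / split has its own reproducible stream.
deriveSeed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 16807
  as.integer(s %% 2147483629) + 1L
}

# Stable hash of an R object (via canonical JSON + md5 of a temp file);
# used to stamp run manifests.
configHash <- function(x) {
  j <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(as.character(j), f)
  unname(tools::md5sum(f))
}

assertBinaryMask <- function(m, arg = deparse(substitute(m))) {
  if (!is.matrix(m) || !all(m %in% c(0, 1)))
    stop(sprintf("'%s' must be a binary (0/1) matrix", arg), call. = FALSE)
  invisible(m)
}

writeManifest <- function(dir, config, seed, extra = list()) {
  man <- c(list(
    package = "lungfields",
    version = as.character(packageVersion("lungfields")),
    seed = seed,
    config_hash = configHash(config),
    config = config
  ), extra)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}
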