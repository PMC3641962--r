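# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Derive a per-run seed from a base seed, kept inside 32-bit integer range.
derive_seed <- function(base, k) {
  as.integer((as.numeric(base) * 7919 + as.numeric(k)) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a numeric matrix with unique row and column names; the shape every
# pipeline stage consumes.
check_matrix <- function(x, what = "descriptor matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have row names (compound ids) and column names (descriptors)",
         call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate compound ids in ", what, call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate descriptor names in ", what, call. = FALSE)
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

check_labels <- function(labels, ids = NULL) {
  labels <- normalize_labels(labels)
  if (!is.null(ids)) {
    if (is.null(names(labels)))
      stop("labels must be named by compound id", call. = FALSE)
    missing <- setdiff(ids, names(labels))
    if (length(missing))
      stop("labels missing for compounds: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    labels <- labels[ids]
  }
  labels
}

# Canonical class vocabulary with the aliases accepted in label tables.
LABEL_SUBSTRATE <- "substrate"
LABEL_NONSUBSTRATE <- "non-substrate"

normalize_labels <- function(x, context = "label") {
  nm <- names(x)
  x <- tolower(trimws(as.character(x)))
  sub_alias <- c("substrate", "s", "1", "pos", "positive", "yes", "true")
  non_alias <- c("non-substrate", "nonsubstrate", "non_substrate", "non substrate",
                 "n", "0", "neg", "negative", "no", "false")
  out <- ifelse(x %in% sub_alias, LABEL_SUBSTRATE,
                ifelse(x %in% non_alias, LABEL_NONSUBSTRATE, NA_character_))
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop("unknown ", context, " token '", x[bad], "' at position ", bad,
         "; expected 'substrate' or 'non-substrate' (or documented aliases)",
         call. = FALSE)
  }
  names(out) <- nm
  out
}

# Fraction of the majority class; the no-information accuracy baseline.
majority_rate <- function(labels) {
  max(table(labels)) / length(labels)
}

# Sniff a delimiter (tab or comma) from the header line of a delimited file.
read_delim_sniff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0)
    stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", strip.white = TRUE)
}
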