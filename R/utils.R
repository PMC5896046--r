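`%||%` <- function(x, y) if (is.null(x)) y else x

mif_abort <- function(message, class = "psimif_error", ...) {
  cnd <- structure(
    class = c(class, "psimif_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cnd)
}

chk_string <- function(x, what, allow_null = FALSE, allow_empty = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    mif_abort(sprintf("`%s` must be supplied", what))
  }
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    mif_abort(sprintf("`%s` must be a single string", what))
  }
  if (!allow_empty && !nzchar(x)) {
    mif_abort(sprintf("`%s` must be non-empty", what))
  }
  invisible(x)
}

chk_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    mif_abort(sprintf("`%s` must be TRUE or FALSE", what))
  }
  invisible(x)
}

chk_id <- function(x, what, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    mif_abort(sprintf("`%s` must be supplied", what))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x)) {
    mif_abort(sprintf("`%s` must be a single integer id", what))
  }
  invisible(as.integer(x))
}

chk_num <- function(x, what, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    mif_abort(sprintf("`%s` must be supplied", what))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    mif_abort(sprintf("`%s` must be a single number", what))
  }
  invisible(as.numeric(x))
}

chk_list_of <- function(x, cls, what) {
  if (is.null(x)) return(list())
  if (inherits(x, cls)) x <- list(x)
  if (!is.list(x)) mif_abort(sprintf("`%s` must be a list of <%s>", what, cls))
  for (el in x) {
    if (!inherits(el, cls)) {
      mif_abort(sprintf("`%s` must contain only <%s> objects", what, cls))
    }
  }
  unname(x)
}

is_mi_accession <- function(x) {
  is.character(x) && length(x) == 1L && grepl("^MI:[0-9]{4}$", x)
}

# XML text escaping for element content and attribute values
xesc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# format a double the way it went in, if a lexical form was retained
num_lex <- function(value, lexical = NULL) {
  if (!is.null(lexical)) return(lexical)
  format(value, scientific = FALSE, trim = TRUE)
}
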