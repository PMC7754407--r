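`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

#' Read a value from a nested configuration list by dot-path
#'
#' Parameter paths such as `"costs.conditions.depression.direct"` address
#' scalar inputs inside the nested model configuration; sensitivity analyses
#' use them to perturb a single input at a time.
#'
#' @param config a nested list (see [load_config()]).
#' @param path character scalar, keys separated by `.`. List entries inside
#'   unnamed lists (e.g. the scenario list) are addressed by 1-based index.
#' @return the value stored at `path`.
#' @export
config_get <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  node <- config
  for (k in keys) {
    idx <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
    if (is.character(idx) && (is.null(names(node)) || !idx %in% names(node))) {
      stop_input("configuration parameter path not found: '", path,
                 "' (missing key '", k, "')")
    }
    node <- node[[idx]]
    if (is.null(node)) {
      stop_input("configuration parameter path not found: '", path,
                 "' (missing key '", k, "')")
    }
  }
  node
}

#' @rdname config_get
#' @param value replacement value.
#' @return `config_set` returns the modified configuration list.
#' @export
config_set <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  config_get(config, path)  # existence check, errors with the offending key
  set_rec <- function(node, keys) {
    k <- keys[[1L]]
    idx <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
    if (length(keys) == 1L) {
      node[[idx]] <- value
    } else {
      node[[idx]] <- set_rec(node[[idx]], keys[-1L])
    }
    node
  }
  set_rec(config, keys)
}
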