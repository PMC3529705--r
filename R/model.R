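#' Compartmental biokinetic models
#'
#' A `compartmental_model` is a linear first-order compartmental system:
#' named compartments connected by directed transfers, each transfer carrying
#' an integer rate index. The dynamics are
#' \deqn{dy_j/dt = \sum_{\alpha \in A_j^+} x_\alpha y_{[x_\alpha]}(t)
#'               - \sum_{\beta \in A_j^-} x_\beta y_j(t),}
#' i.e. mass flows between compartments at first-order rates (1/day), with
#' the whole ingested amount (100\%) initially in the stomach entry
#' compartment and two absorbing excreta compartments (urine, feces).
#'
#' @param name model label.
#' @param compartments character vector of compartment labels (order fixes
#'   the row/column order of system matrices).
#' @param transfers data frame with columns `rate` (integer index), `source`,
#'   `target` (compartment labels).
#' @param entry label of the entry (stomach) compartment.
#' @param terminals labels of absorbing excreta compartments.
#' @param plasma label of the plasma (transfer) compartment.
#' @param bones labels of the bone compartment(s).
#' @param compartment_names optional named character vector of descriptive
#'   compartment names.
#'
#' @return An object of class `compartmental_model`.
#' @export
compartmental_model <- function(name, compartments, transfers, entry,
                                terminals, plasma, bones,
                                compartment_names = NULL) {
  transfers <- as.data.frame(transfers)
  stopifnot(all(c("rate", "source", "target") %in% names(transfers)))
  transfers$rate <- as.integer(transfers$rate)
  m <- structure(
    list(name = name,
         compartments = as.character(compartments),
         transfers = transfers[, c("rate", "source", "target")],
         entry = entry,
         terminals = as.character(terminals),
         plasma = plasma,
         bones = as.character(bones),
         compartment_names = compartment_names),
    class = "compartmental_model")
  validate_model(m)
  m
}

#' Validate the structural invariants of a compartmental model
#'
#' Checks, and stops with an informative error on violation:
#' distinct declared source/target per transfer, unique rate indices,
#' absorbing terminal compartments (no outgoing transfers), entry compartment
#' with a single outgoing transfer, and declared plasma/bone/entry/terminal
#' labels all present in the compartment list.
#'
#' @param m a `compartmental_model`.
#' @return `m`, invisibly.
#' @export
validate_model <- function(m) {
  tr <- m$transfers
  comp <- m$compartments
  bad <- setdiff(c(tr$source, tr$target, m$entry, m$terminals, m$plasma,
                   m$bones), comp)
  if (length(bad))
    stop("undeclared compartment label(s): ", paste(bad, collapse = ", "))
  if (any(tr$source == tr$target))
    stop("self-transfer(s) at rate index ",
         paste(tr$rate[tr$source == tr$target], collapse = ", "))
  if (anyDuplicated(tr$rate))
    stop("duplicated rate indices: ",
         paste(unique(tr$rate[duplicated(tr$rate)]), collapse = ", "))
  out_term <- tr$rate[tr$source %in% m$terminals]
  if (length(out_term))
    stop("terminal compartment has outgoing transfer(s), rate index ",
         paste(out_term, collapse = ", "))
  entry_out <- tr[tr$source == m$entry, , drop = FALSE]
  if (nrow(entry_out) != 1L)
    stop("entry compartment must have exactly one outgoing transfer, found ",
         nrow(entry_out))
  invisible(m)
}

#' @export
print.compartmental_model <- function(x, ...) {
  cat(sprintf("<compartmental_model> %s: %d compartments, %d transfers\n",
              x$name, length(x$compartments), nrow(x$transfers)))
  cat("  entry:", x$entry, " terminals:", paste(x$terminals, collapse = ","),
      " plasma:", x$plasma, " bones:", paste(x$bones, collapse = ","), "\n")
  invisible(x)
}

#' Rate indices declared by a model
#' @param m a `compartmental_model`.
#' @return sorted integer vector of rate indices.
#' @export
rate_indices <- function(m) sort(m$transfers$rate)

#' Read a compartmental model definition from JSON
#'
#' The file carries keys `name`, `compartments`, `transfers`
#' (`[{rate, source, target}]`), `entry`, `terminals`, `plasma`, `bones`.
#' Structural invariants are enforced at load time.
#'
#' @param path path to a model JSON file.
#' @return a `compartmental_model`.
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cn <- if (!is.null(j$compartment_names)) unlist(j$compartment_names)
  compartmental_model(j$name, j$compartments, j$transfers, j$entry,
                      j$terminals, j$plasma, j$bones, compartment_names = cn)
}

#' Load a bundled biokinetic model
#'
#' Two model structures ship with the package, both best-effort
#' reconstructions of the published wiring (the originals are not deposited):
#' `"icrp"` — 11 compartments, 15 transfers (rate indices 1-8, 13-19), two
#' bone-surface compartments with direct transfers to the urinary bladder
#' contents and the upper large intestine; `"hmgu"` — 10 compartments, 12
#' transfers (rate indices 1-12), a single combined bone compartment
#' exchanging with plasma. Indices 1-8 name the structurally shared
#' transfers.
#'
#' @param which `"icrp"` or `"hmgu"`.
#' @return a `compartmental_model`.
#' @examples
#' zr_model("hmgu")
#' @export
zr_model <- function(which = c("hmgu", "icrp")) {
  which <- match.arg(which)
  path <- system.file("extdata", "models", paste0(which, ".json"),
                      package = "zirbayes", mustWork = TRUE)
  read_model_json(path)
}

#' Rate vectors
#'
#' A `rate_vector` maps a model's rate indices to nonnegative transfer rates
#' (1/day). The index set must match the model's declared indices exactly.
#'
#' @param model a `compartmental_model`.
#' @param values numeric vector of rates, named by rate index (names may be
#'   bare integers); or an unnamed vector in the order of
#'   `rate_indices(model)`.
#' @return a named numeric vector of class `rate_vector` with attribute
#'   `model` holding the model name.
#' @export
rate_vector <- function(model, values) {
  idx <- rate_indices(model)
  if (is.null(names(values))) {
    if (length(values) != length(idx))
      stop("expected ", length(idx), " rates for model ", model$name,
           ", got ", length(values))
    names(values) <- as.character(idx)
  }
  got <- sort(as.integer(names(values)))
  if (!identical(got, idx)) {
    miss <- setdiff(idx, got); extra <- setdiff(got, idx)
    stop("rate index mismatch for model ", model$name,
         if (length(miss)) paste0("; missing: ", paste(miss, collapse = ",")),
         if (length(extra)) paste0("; extra: ", paste(extra, collapse = ",")))
  }
  if (any(values < 0)) stop("negative rate(s)")
  structure(as.numeric(values)[order(as.integer(names(values)))],
            names = as.character(idx),
            model = model$name, class = "rate_vector")
}
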