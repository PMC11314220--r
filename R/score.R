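#' Construct a genetic score model
#'
#' An affine predictor of adipose alpha-tocopherol concentration from coded
#' genotypes: `score = intercept + sum_i r_i * c_i`, where `c_i` is the
#' minor-allele count for additively coded SNPs and the carrier indicator
#' (dosage 2 collapsed to 1) for dominantly coded SNPs.
#'
#' @param intercept concentration at the zero-minor-allele genotype
#'   (nmol/g protein).
#' @param entries data frame with columns `snp`, `coding`
#'   (`"additive"`/`"dominant"`) and `coefficient`; optional `gene`, `vip`.
#' @return object of class `genetic_score`.
#' @seealso [predict.genetic_score()], [score_from_fit()], [atoc_score()]
#' @export
genetic_score <- function(intercept, entries) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.data.frame(entries),
            all(c("snp", "coding", "coefficient") %in% names(entries)))
  if (anyDuplicated(entries$snp)) {
    stop("score entries must have unique SNP ids")
  }
  if (!all(entries$coding %in% c("additive", "dominant"))) {
    stop("coding must be 'additive' or 'dominant'")
  }
  structure(list(intercept = intercept,
                 entries = as.data.frame(entries, stringsAsFactors = FALSE)),
            class = "genetic_score")
}

#' @export
print.genetic_score <- function(x, ...) {
  cat(sprintf("Genetic score: intercept %.4g + %d SNP term(s)\n",
              x$intercept, nrow(x$entries)))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Apply a genetic score to genotypes
#'
#' @param object a [genetic_score()] model.
#' @param genotypes dosage matrix (participants x SNPs) or a single named
#'   dosage vector covering the model SNPs.
#' @param impute_missing when `TRUE`, missing genotypes at model SNPs are
#'   replaced by the column mean dosage of the supplied matrix (flagged in
#'   the result's `"imputed"` attribute); by default missing genotypes are
#'   an error listing the offending SNPs.
#' @param ... unused.
#' @return named numeric vector of predicted concentrations (nmol/g
#'   protein).
#' @export
predict.genetic_score <- function(object, genotypes, impute_missing = FALSE,
                                  ...) {
  if (is.null(dim(genotypes))) {
    genotypes <- matrix(genotypes, nrow = 1,
                        dimnames = list(NULL, names(genotypes)))
  }
  need <- object$entries$snp
  missing_cols <- setdiff(need, colnames(genotypes))
  if (length(missing_cols)) {
    stop("genotypes lack model SNP(s): ",
         paste(missing_cols, collapse = ", "))
  }
  g <- genotypes[, need, drop = FALSE]
  imputed <- FALSE
  if (anyNA(g)) {
    if (!impute_missing) {
      bad <- need[colSums(is.na(g)) > 0]
      stop("missing genotypes at model SNP(s): ",
           paste(bad, collapse = ", "),
           " (set impute_missing = TRUE for mean-dosage fallback)")
    }
    for (j in seq_len(ncol(g))) {
      nas <- is.na(g[, j])
      if (any(nas)) {
        g[nas, j] <- mean(g[, j], na.rm = TRUE)
        imputed <- TRUE
      }
    }
  }
  coded <- g
  dom <- object$entries$coding == "dominant"
  coded[, dom] <- pmin(coded[, dom, drop = FALSE], 1)
  out <- object$intercept + drop(coded %*% object$entries$coefficient)
  names(out) <- rownames(genotypes)
  if (imputed) {
    attr(out, "imputed") <- TRUE
  }
  out
}

#' Export a fitted selection as a genetic score
#'
#' Converts the final PLS model of a [vip_select()] result (or a bare
#' [pls1()] fit plus variable metadata) into a [genetic_score()]: the
#' unstandardized intercept and per-SNP coefficients with their codings.
#' Scoring the training genotypes with the export reproduces the model's
#' predictions exactly. Covariate terms cannot enter a genetic score; they
#' are returned in the `"covariates"` attribute with a warning and the score
#' is restricted to the genetic part.
#'
#' @param fit a `vip_selection` or `pls1` object.
#' @param variable_meta data frame mapping `variable` to `snp` and `model`;
#'   taken from the selection object when omitted.
#' @return a `genetic_score`; covariate coefficients, if any, in attribute
#'   `"covariates"`.
#' @export
score_from_fit <- function(fit, variable_meta = NULL) {
  if (inherits(fit, "vip_selection")) {
    if (!isTRUE(fit$selected)) {
      stop("no model was selected; nothing to export")
    }
    variable_meta <- fit$variable_meta
    model <- fit$final_model
  } else if (inherits(fit, "pls1")) {
    model <- fit
    if (is.null(variable_meta)) {
      vars <- names(model$coefficients)
      variable_meta <- data.frame(
        variable = vars, snp = sub("_(add|dom)$", "", vars),
        model = ifelse(grepl("_dom$", vars), "dominant", "additive"),
        stringsAsFactors = FALSE)
      variable_meta$snp[!grepl("_(add|dom)$", vars)] <- NA_character_
    }
  } else {
    stop("fit must be a 'vip_selection' or 'pls1' object")
  }
  b <- model$coefficients
  meta <- variable_meta[match(names(b), variable_meta$variable), ]
  is_snp <- !is.na(meta$snp)
  covariates <- NULL
  if (any(!is_snp)) {
    warning("covariate term(s) exported separately; the genetic score is ",
            "restricted to SNP terms: ",
            paste(names(b)[!is_snp], collapse = ", "))
    covariates <- b[!is_snp]
  }
  gs <- genetic_score(
    intercept = model$intercept,
    entries = data.frame(snp = meta$snp[is_snp],
                         coding = meta$model[is_snp],
                         coefficient = unname(b[is_snp]),
                         vip = unname(model$vip[is_snp]),
                         stringsAsFactors = FALSE))
  attr(gs, "covariates") <- covariates
  gs
}

#' The published adipose alpha-tocopherol genetic score
#'
#' Loads the packaged 10-SNP score model (intercept 35.7 nmol/g protein plus
#' per-SNP coefficients with additive or dominant coding) so the published
#' score is runnable out of the box.
#'
#' @return a [genetic_score()] object.
#' @examples
#' gs <- atoc_score()
#' zero <- stats::setNames(rep(0, nrow(gs$entries)), gs$entries$snp)
#' predict(gs, zero) # intercept only
#' @export
atoc_score <- function() {
  path <- system.file("extdata", "atoc_score_model.json", package = "tocopls",
                      mustWork = TRUE)
  read_score_model(path)
}

#' Read and write genetic score models as JSON
#'
#' The serialization round-trips exactly: intercept, entries (snp, coding,
#' coefficient, optional gene and vip).
#'
#' @param path file path.
#' @param model a `genetic_score` object (for writing).
#' @return `read_score_model` returns a `genetic_score`;
#'   `write_score_model` returns `path` invisibly.
#' @export
read_score_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  genetic_score(obj$intercept, obj$entries)
}

#' @rdname read_score_model
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "genetic_score"))
  jsonlite::write_json(
    list(intercept = model$intercept, entries = model$entries),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
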