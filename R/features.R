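#' @include AllClasses.R
NULL

FEATURE_CLASSES <- c("linear", "quadratic", "product", "hinge")

#' Parse a compact feature-class code
#'
#' \code{"LQH"} means linear + quadratic + hinge, etc. A character vector
#' of full class names passes through unchanged.
#' @noRd
parseClasses <- function(classes) {
  if (length(classes) == 1L && grepl("^[LQPH]+$", classes)) {
    map <- c(L = "linear", Q = "quadratic", P = "product", H = "hinge")
    classes <- unname(map[strsplit(classes, "")[[1]]])
  }
  bad <- setdiff(classes, FEATURE_CLASSES)
  if (length(bad)) stop("unknown feature class: ", paste(bad, collapse = ","))
  unique(classes)
}

#' Default feature classes by presence count (MaxEnt 3.4.1 auto rule)
#'
#' Fewer than 10 presences: linear only; 10-14: linear + quadratic;
#' 15-79: linear + quadratic + hinge; 80 or more: all four classes.
#'
#' @param nPresence number of presence records
#' @return character vector of feature class names
#' @export
autoFeatureClasses <- function(nPresence) {
  if (nPresence < 10) c("linear")
  else if (nPresence < 15) c("linear", "quadratic")
  else if (nPresence < 80) c("linear", "quadratic", "hinge")
  else FEATURE_CLASSES
}

#' Build a feature expansion from training climate values
#'
#' Variables are min-max scaled onto [0,1] using the training range, then
#' expanded: linear = scaled value; quadratic = its square; product =
#' pairwise products of scaled variables; hinge = forward and reverse
#' hinges \eqn{\max(0, (x-k)/(max-k))} and \eqn{\max(0, (k-x)/(k-min))}
#' at \code{nHingeKnots} evenly spaced interior knots per variable. All
#' features lie in [0,1] on the training data.
#'
#' @param values numeric training matrix (presences + background), one
#'   column per climate variable, finite values
#' @param classes feature classes to use; compact codes like \code{"LQH"}
#'   are accepted
#' @param nHingeKnots knots per variable when hinge is requested (>= 2)
#' @return list with \code{features} (matrix) and \code{expansion}
#'   (feature-expansion descriptor reusable on new data)
#' @export
buildFeatures <- function(values, classes = "LQ", nHingeKnots = 8) {
  classes <- parseClasses(classes)
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("values must have variable names")
  if (any(!is.finite(values))) stop("non-finite training values")
  vmin <- apply(values, 2L, min)
  vmax <- apply(values, 2L, max)
  flat <- colnames(values)[vmax - vmin <= 0]
  if (length(flat))
    stop("zero-variance variable(s): ", paste(flat, collapse = ", "))
  if ("hinge" %in% classes && nHingeKnots < 2)
    stop("nHingeKnots must be >= 2 when hinge features are requested")
  knots <- if ("hinge" %in% classes)
    seq(0, 1, length.out = nHingeKnots + 2L)[2:(nHingeKnots + 1L)]
  else numeric()
  expansion <- list(classes = classes, varNames = colnames(values),
                    varMin = vmin, varMax = vmax,
                    nHingeKnots = nHingeKnots, hingeKnots = knots)
  feats <- applyFeatures(expansion, values, clamp = FALSE)
  expansion$featureNames <- colnames(feats)
  list(features = feats, expansion = expansion)
}

#' Evaluate a feature expansion on new climate values
#'
#' @param expansion an expansion from \code{\link{buildFeatures}}
#' @param values numeric matrix carrying at least the expansion's
#'   variables (matched by name)
#' @param clamp truncate scaled variables into [0,1] (the training range)
#'   before expansion
#' @return list-free feature matrix; attribute \code{"clamped"} is a
#'   logical vector marking rows where any variable was clamped
#' @export
applyFeatures <- function(expansion, values, clamp = TRUE) {
  values <- as.matrix(values)
  missing <- setdiff(expansion$varNames, colnames(values))
  if (length(missing))
    stop("missing variable(s): ", paste(missing, collapse = ", "))
  X <- values[, expansion$varNames, drop = FALSE]
  S <- sweep(X, 2L, expansion$varMin)
  S <- sweep(S, 2L, expansion$varMax - expansion$varMin, "/")
  clampedRow <- rowSums(S < 0 | S > 1) > 0
  if (clamp) S <- pmin(pmax(S, 0), 1)
  p <- ncol(S); vn <- expansion$varNames
  cols <- list(); nms <- character()
  cl <- expansion$classes
  if ("linear" %in% cl) { cols <- c(cols, list(S)); nms <- c(nms, vn) }
  if ("quadratic" %in% cl) {
    cols <- c(cols, list(S^2)); nms <- c(nms, paste0(vn, "^2"))
  }
  if ("product" %in% cl && p >= 2L) {
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
      cols <- c(cols, list(S[, i] * S[, j]))
      nms <- c(nms, paste0(vn[i], "*", vn[j]))
    }
  }
  if ("hinge" %in% cl) {
    for (k in expansion$hingeKnots) {
      cols <- c(cols, list(pmax(sweep(S, 2L, k) / (1 - k), 0)))
      nms <- c(nms, sprintf("hf(%s,%.4f)", vn, k))
    }
    for (k in expansion$hingeKnots) {
      cols <- c(cols, list(pmax(sweep(-S, 2L, -k) / k, 0)))
      nms <- c(nms, sprintf("hr(%s,%.4f)", vn, k))
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- nms
  attr(out, "clamped") <- clampedRow
  out
}

#' Class label of every feature column of an expansion
#'
#' Companion to \code{\link{buildFeatures}}: returns, in column order,
#' which feature class each column belongs to — the input needed to
#' compute per-class regularization weights.
#'
#' @param expansion an expansion from \code{\link{buildFeatures}}
#' @return character vector, one entry per feature column
#' @export
featureColumnClasses <- function(expansion) {
  p <- length(expansion$varNames)
  cl <- expansion$classes
  out <- character()
  if ("linear" %in% cl) out <- c(out, rep("linear", p))
  if ("quadratic" %in% cl) out <- c(out, rep("quadratic", p))
  if ("product" %in% cl && p >= 2L)
    out <- c(out, rep("product", p * (p - 1L) / 2L))
  if ("hinge" %in% cl)
    out <- c(out, rep("hinge", 2L * p * expansion$nHingeKnots))
  out
}
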