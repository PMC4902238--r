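#' Label H2SOM prototypes from sparse annotations
#'
#' Assigns every labelled feature vector to its exhaustive best matching unit,
#' counts per prototype the assigned vectors (`q`) and the positive --
#' live/stressed -- ones (`q_plus`), and scores each prototype by
#' `s = q_plus / q`, the fraction of its Voronoi cell carrying positive
#' labels. Prototypes are ranked by descending `s` (ties: larger `q_plus`,
#' then lower node id) and the minimal prefix whose summed `q_plus` covers at
#' least `coverage_target` of all positive vectors is selected as the
#' "live-like" prototype set.
#'
#' @param model A fitted [h2som()].
#' @param x Feature matrix (all labelled features), or a `training_set`.
#' @param y Binary labels (1 = live/stressed); ignored when `x` is a
#'   `training_set`.
#' @param coverage_target Fraction of positive vectors the selected prototypes
#'   must cover (default 0.8).
#' @return A `label_model`: per-node `q`, `q_plus`, `s`, the `ranking`, the
#'   `selected` node ids and `L = length(selected)`.
#' @export
fit_label_model <- function(model, x, y = NULL, coverage_target = 0.8) {
  if (inherits(x, "training_set")) { y <- x$y; x <- x$X }
  stopifnot(isTRUE(model$trained), length(y) == nrow(x),
            coverage_target > 0, coverage_target <= 1)
  y <- as.integer(y)
  if (sum(y) == 0L) stop("no positive labels; cannot map prototypes")
  m <- nrow(model$prototypes)
  id <- bmu(model, x)
  q <- tabulate(id, nbins = m)
  q_plus <- tabulate(id[y == 1L], nbins = m)
  s <- ifelse(q > 0, q_plus / q, 0)
  ranking <- order(-s, -q_plus, seq_len(m))
  covered <- cumsum(q_plus[ranking])
  L <- which(covered >= coverage_target * sum(q_plus))[1]
  structure(list(q = q, q_plus = q_plus, s = s, ranking = ranking,
                 selected = ranking[seq_len(L)], L = L,
                 coverage_target = coverage_target,
                 coverage = covered[L] / sum(q_plus)),
            class = "label_model")
}

#' @export
print.label_model <- function(x, ...) {
  cat(sprintf(
    "<label_model: %d prototype(s) selected, %.1f%% positive coverage (target %.0f%%)>\n",
    x$L, 100 * x$coverage, 100 * x$coverage_target))
  invisible(x)
}

#' Segment an image into live-algae pixels
#'
#' Computes grid features ([extract_features()]), finds each grid position's
#' exhaustive BMU and marks it positive iff the BMU belongs to the label
#' model's selected prototype set. Grid decisions are expanded to full image
#' resolution by nearest-grid assignment.
#'
#' @param img A (preprocessed) [raster_image()].
#' @param model A fitted [h2som()].
#' @param lm A [fit_label_model()] result.
#' @param stride Feature grid stride (must match the training stride).
#' @return Binary `height x width` matrix of class `segmentation_mask` with
#'   attributes `image_id` and `post_processed = FALSE`.
#' @export
classify_image <- function(img, model, lm, stride = 2L) {
  fs <- extract_features(img, stride = stride)
  ids <- bmu(model, fs$X)
  pos <- ids %in% lm$selected
  ny <- length(unique(fs$y))
  nx <- length(unique(fs$x))
  grid <- matrix(pos, ny, nx)
  d <- dim(img)
  yi <- pmin(ny, round((seq_len(d[1]) - 1L) / stride) + 1L)
  xi <- pmin(nx, round((seq_len(d[2]) - 1L) / stride) + 1L)
  mask <- grid[yi, xi, drop = FALSE] * 1
  structure(mask, image_id = image_id(img), post_processed = FALSE,
            class = c("segmentation_mask", "matrix", "array"))
}

#' Score a segmentation against sparse annotations
#'
#' Builds pixel sets from the annotation rows of this image (points and
#' rectangle interiors): positives `p+` from live/stressed labels, negatives
#' `p-` from dead and bare labels. Reports recall
#' `|p+ ∩ ps| / |p+|`, precision `|p+ ∩ ps| / |ps|` (over annotated pixels),
#' and false positive rates over all negatives and for dead and bare
#' separately. Empty denominators yield `NA`, never 0. Precision under sparse
#' example-based labelling is non-diagnostic (most segmented pixels are
#' unlabelled); recall and FPR are the meaningful scores.
#'
#' @param mask Binary segmentation mask.
#' @param annotations Annotation data frame ([emit_annotations()] dialect).
#' @param image_id Image id to score (default: the mask's).
#' @return One-row data frame: `recall`, `precision`, `fpr_all`, `fpr_dead`,
#'   `fpr_bare`, plus pixel counts.
#' @export
evaluate_segmentation <- function(mask, annotations,
                                  image_id = attr(mask, "image_id")) {
  ann <- annotations[annotations$image_id == image_id, , drop = FALSE]
  h <- nrow(mask); w <- ncol(mask)
  pix <- function(rows) {
    if (nrow(rows) == 0L) return(logical(h * w))
    m <- matrix(FALSE, h, w)
    for (i in seq_len(nrow(rows))) {
      a <- rows[i, ]
      if (a$shape == "point") {
        m[a$y, a$x] <- TRUE
      } else {
        ys <- a$y:min(h, a$y + a$h - 1L)
        xs <- a$x:min(w, a$x + a$w - 1L)
        m[ys, xs] <- TRUE
      }
    }
    as.vector(m)
  }
  pos <- pix(ann[ann$label %in% c("live", "stressed"), , drop = FALSE])
  dead <- pix(ann[ann$label == "dead", , drop = FALSE])
  bare <- pix(ann[ann$label == "bare", , drop = FALSE])
  neg <- dead | bare
  seg <- as.vector(mask > 0)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  data.frame(recall = rate(sum(pos & seg), sum(pos)),
             precision = rate(sum(pos & seg), sum(seg)),
             fpr_all = rate(sum(neg & seg), sum(neg)),
             fpr_dead = rate(sum(dead & seg), sum(dead)),
             fpr_bare = rate(sum(bare & seg), sum(bare)),
             n_pos = sum(pos), n_neg = sum(neg))
}
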