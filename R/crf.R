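#' Training configuration for the chain CRF tagger
#'
#' @param seed Integer seed recorded in the model metadata and used to
#'   derive per-fold seeds in [leave_one_out()].  Training itself is
#'   deterministic (weights start at zero and the objective is convex), so
#'   identical configurations always give identical models.
#' @param l2 L2 regularization strength (lambda/2 * ||w||^2 added to the
#'   negative log-likelihood).  Default 0.1.
#' @param max_iter Iteration cap for the L-BFGS optimizer.  Default 200.
#' @param window Context window half-width for features; the four features
#'   of the tokens at offsets -window..window are included.  Default 1.
#' @return A list of class \code{chem_crf_config}.
#' @export
crf_config <- function(seed = 42L, l2 = 0.1, max_iter = 200L, window = 1L) {
  stopifnot(l2 >= 0, max_iter >= 1, window >= 0)
  structure(list(seed = as.integer(seed), l2 = l2,
                 max_iter = as.integer(max_iter), window = as.integer(window)),
            class = "chem_crf_config")
}

CRF_TEMPLATE_VERSION <- "stem-prefix-suffix-number/w1/v1"

# feature strings for one document's feature table
crf_feature_strings <- function(feats, window = 1L) {
  n <- nrow(feats)
  cols <- list(stem = feats$stem, pre = feats$prefix, suf = feats$suffix,
               num = as.character(feats$is_number))
  base <- lapply(seq_len(n), function(t) character(0))
  for (off in -window:window) {
    idx <- seq_len(n) + off
    ok <- idx >= 1L & idx <= n
    tagp <- paste0("w", ifelse(off > 0, "+", ""), off, ".")
    for (nm in names(cols)) {
      v <- rep(paste0(tagp, if (off < 0) "BOS" else "EOS"), n)
      v[ok] <- paste0(tagp, nm, "=", cols[[nm]][idx[ok]])
      base <- Map(c, base, v)
    }
  }
  lapply(base, unique)
}

crf_prepare_doc <- function(doc, window) {
  tokens <- tokenize(doc$text)
  tags <- tryCatch(spans_to_tags(tokens, doc$entities),
                   error = function(e) stop("document ", doc$doc_id, ": ",
                                            conditionMessage(e), call. = FALSE))
  list(tokens = tokens, tags = tags,
       fstr = crf_feature_strings(extract_features(tokens), window))
}

# sparse design matrix (tokens x features) from feature-index lists
crf_design <- function(fidx, n_feat) {
  lens <- lengths(fidx)
  Matrix::sparseMatrix(i = rep(seq_along(fidx), lens),
                       j = unlist(fidx, use.names = FALSE), x = 1,
                       dims = c(length(fidx), n_feat))
}

lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
col_lse <- function(M) {
  m <- apply(M, 2, max)
  m + log(colSums(exp(sweep(M, 2, m))))
}
row_lse <- function(M) col_lse(t(M))

# forward-backward in log space; returns logZ, posteriors P (n x K) and
# summed pairwise transition posteriors (K x K)
crf_forward_backward <- function(E, Tr) {
  n <- nrow(E); K <- ncol(E)
  Tk <- Tr[seq_len(K), , drop = FALSE]
  alpha <- matrix(0, n, K); beta <- matrix(0, n, K)
  alpha[1, ] <- Tr[K + 1L, ] + E[1, ]
  if (n > 1) for (t in 2:n)
    alpha[t, ] <- col_lse(alpha[t - 1L, ] + Tk) + E[t, ]
  logZ <- lse(alpha[n, ])
  if (n > 1) for (t in (n - 1L):1L)
    beta[t, ] <- row_lse(sweep(Tk, 2, E[t + 1L, ] + beta[t + 1L, ], "+"))
  P <- exp(alpha + beta - logZ)
  Qsum <- matrix(0, K, K)
  if (n > 1) for (t in 2:n) {
    Q <- sweep(Tk, 1, alpha[t - 1L, ], "+")
    Q <- sweep(Q, 2, E[t, ] + beta[t, ], "+")
    Qsum <- Qsum + exp(Q - logZ)
  }
  list(logZ = logZ, P = P, Qsum = Qsum)
}

#' Fit a linear-chain CRF chemical entity tagger
#'
#' A first-order, linear-chain conditional random field over the five-tag
#' encoding (see [spans_to_tags()]).  State features are indicator
#' features of the stem/prefix/suffix/is-number quadruple of the current
#' token and of its neighbours in a +/-\code{window} context; transition
#' weights cover all tag bigrams plus a begin-of-sequence row.  The convex,
#' L2-penalized negative log-likelihood is minimized with L-BFGS from a
#' zero start, so training is reproducible bit-for-bit given the same
#' corpus and configuration; the metadata needed to do so (feature template
#' version, hyperparameters, seed, training document ids) is stored on the
#' model.
#'
#' @param corpus A \code{chem_corpus} (or list of \code{chem_doc}) with at
#'   least one document; all entities must be token-aligned.
#' @param config A [crf_config()].
#' @return An object of class \code{chem_crf} with [predict.chem_crf()]
#'   and [print.chem_crf()] methods.
#' @export
crf_train <- function(corpus, config = crf_config()) {
  if (length(corpus) == 0) stop("cannot train on an empty corpus")
  K <- length(CHEM_TAGS)
  prep <- lapply(corpus, crf_prepare_doc, window = config$window)
  prep <- prep[vapply(prep, function(p) nrow(p$tokens) > 0, TRUE)]
  if (!length(prep)) stop("corpus contains no tokens")
  feat_names <- unique(unlist(lapply(prep, function(p)
    unlist(p$fstr, use.names = FALSE)), use.names = FALSE))
  Ft <- length(feat_names)
  seqs <- lapply(prep, function(p) {
    fidx <- lapply(p$fstr, function(v) match(v, feat_names))
    list(X = crf_design(fidx, Ft), y = match(p$tags, CHEM_TAGS),
         Y = diag(K)[match(p$tags, CHEM_TAGS), , drop = FALSE])
  })
  npar <- Ft * K + (K + 1L) * K
  unpack <- function(par) list(
    W = matrix(par[seq_len(Ft * K)], Ft, K),
    Tr = matrix(par[Ft * K + seq_len((K + 1L) * K)], K + 1L, K))
  cache <- new.env(parent = emptyenv())
  compute <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return()
    th <- unpack(par)
    nll <- 0
    gW <- matrix(0, Ft, K); gT <- matrix(0, K + 1L, K)
    for (s in seqs) {
      E <- as.matrix(s$X %*% th$W)
      fb <- crf_forward_backward(E, th$Tr)
      n <- nrow(E); y <- s$y
      gold <- th$Tr[K + 1L, y[1]] + sum(E[cbind(seq_len(n), y)]) +
        if (n > 1) sum(th$Tr[cbind(y[-n], y[-1])]) else 0
      nll <- nll + fb$logZ - gold
      gW <- gW + as.matrix(Matrix::crossprod(s$X, fb$P - s$Y))
      emp <- matrix(0, K, K)
      if (n > 1) for (t in 2:n) emp[y[t - 1L], y[t]] <- emp[y[t - 1L], y[t]] + 1
      gT[seq_len(K), ] <- gT[seq_len(K), ] + fb$Qsum - emp
      start <- fb$P[1, ]; start[y[1]] <- start[y[1]] - 1
      gT[K + 1L, ] <- gT[K + 1L, ] + start
    }
    cache$par <- par
    cache$value <- nll + config$l2 / 2 * sum(par^2)
    cache$grad <- c(gW, gT) + config$l2 * par
  }
  fit <- stats::optim(rep(0, npar),
                      fn = function(p) { compute(p); cache$value },
                      gr = function(p) { compute(p); cache$grad },
                      method = "L-BFGS-B",
                      control = list(maxit = config$max_iter))
  th <- unpack(fit$par)
  dimnames(th$W) <- list(feat_names, CHEM_TAGS)
  dimnames(th$Tr) <- list(c(CHEM_TAGS, "BOS"), CHEM_TAGS)
  structure(list(
    W = th$W, Tr = th$Tr, features = feat_names, tags = CHEM_TAGS,
    meta = list(template_version = CRF_TEMPLATE_VERSION,
                window = config$window, l2 = config$l2,
                max_iter = config$max_iter, seed = config$seed,
                doc_ids = unname(vapply(corpus, `[[`, "", "doc_id")),
                convergence = fit$convergence, nll = fit$value)),
    class = "chem_crf")
}

#' @exportS3Method base::print
print.chem_crf <- function(x, ...) {
  cat("<chem_crf> linear-chain CRF, ", length(x$features), " features, ",
      "trained on ", length(x$meta$doc_ids), " documents\n",
      "  template ", x$meta$template_version,
      ", l2 = ", x$meta$l2, ", max_iter = ", x$meta$max_iter,
      ", seed = ", x$meta$seed, "\n", sep = "")
  invisible(x)
}

crf_viterbi <- function(E, Tr) {
  n <- nrow(E); K <- ncol(E)
  Tk <- Tr[seq_len(K), , drop = FALSE]
  delta <- matrix(0, n, K); psi <- matrix(0L, n, K)
  delta[1, ] <- Tr[K + 1L, ] + E[1, ]
  if (n > 1) for (t in 2:n) {
    M <- delta[t - 1L, ] + Tk
    psi[t, ] <- apply(M, 2, which.max)
    delta[t, ] <- apply(M, 2, max) + E[t, ]
  }
  y <- integer(n)
  y[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1L):1L) y[t] <- psi[t + 1L, y[t + 1L]]
  y
}

#' Predict chemical entity mentions with a trained CRF
#'
#' Tokenizes the text, extracts the model's feature template, decodes the
#' Viterbi tag sequence and converts it back to character spans.  Predicted
#' mentions carry no lexicon id: resolution is a separate step.
#'
#' @param object A \code{chem_crf} model.
#' @param newdata A character string, or a \code{chem_doc}.
#' @param doc_id Document id for the returned mentions (taken from
#'   \code{newdata} when it is a document).
#' @param ... Unused.
#' @return Mention data frame (possibly empty), with a \code{"repairs"}
#'   attribute from the tag decoder.
#' @export
predict.chem_crf <- function(object, newdata, doc_id = "doc", ...) {
  if (object$meta$template_version != CRF_TEMPLATE_VERSION)
    stop("model was trained with feature template '",
         object$meta$template_version, "', this build uses '",
         CRF_TEMPLATE_VERSION, "'")
  if (inherits(newdata, "chem_doc")) {
    doc_id <- newdata$doc_id
    newdata <- newdata$text
  }
  tokens <- tokenize(newdata)
  if (nrow(tokens) == 0) return(mentions())
  fstr <- crf_feature_strings(extract_features(tokens), object$meta$window)
  fidx <- lapply(fstr, function(v) {
    i <- match(v, object$features)
    i[!is.na(i)]
  })
  X <- crf_design(fidx, length(object$features))
  E <- as.matrix(X %*% object$W)
  y <- crf_viterbi(E, object$Tr)
  tags_to_spans(tokens, object$tags[y], doc_id = doc_id, text = newdata)
}

#' Leave-one-document-out cross-validation
#'
#' Every document is tagged by a model trained on all remaining documents,
#' so no prediction ever comes from a model that saw its own annotations.
#' Per-fold seeds are derived deterministically from \code{config$seed} and
#' the fold index; each fold's model metadata lists the training document
#' ids, never the evaluated one.
#'
#' @param corpus A \code{chem_corpus} with at least two documents.
#' @param config A [crf_config()].
#' @return Named list \code{doc_id -> mention data frame}; attribute
#'   \code{"fold_meta"} holds each fold's model metadata.
#' @export
leave_one_out <- function(corpus, config = crf_config()) {
  if (length(corpus) < 2) stop("leave-one-out needs at least 2 documents")
  doc_ids <- vapply(corpus, `[[`, "", "doc_id")
  preds <- vector("list", length(corpus))
  names(preds) <- doc_ids
  metas <- vector("list", length(corpus))
  for (i in seq_along(corpus)) {
    fold_cfg <- config
    fold_cfg$seed <- (config$seed * 131L + i) %% .Machine$integer.max
    model <- crf_train(corpus[-i], fold_cfg)
    preds[[i]] <- predict(model, corpus[[i]])
    metas[[i]] <- model$meta
  }
  attr(preds, "fold_meta") <- stats::setNames(metas, doc_ids)
  preds
}

#' Persist / restore a CRF model as JSON
#'
#' @param model A \code{chem_crf}.
#' @param path JSON file path.
#' @return \code{path} invisibly; for [read_crf()], the model.
#' @export
write_crf <- function(model, path) {
  jsonlite::write_json(list(W = as.vector(model$W), Tr = as.vector(model$Tr),
                            features = model$features, tags = model$tags,
                            meta = model$meta),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_crf
#' @export
read_crf <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- length(raw$tags)
  Ft <- length(raw$features)
  W <- matrix(raw$W, Ft, K, dimnames = list(raw$features, raw$tags))
  Tr <- matrix(raw$Tr, K + 1L, K,
               dimnames = list(c(raw$tags, "BOS"), raw$tags))
  structure(list(W = W, Tr = Tr, features = raw$features, tags = raw$tags,
                 meta = raw$meta), class = "chem_crf")
}
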