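# Feature-selector and classifier registries. The defaults enumerate 45
# selector entries and 32 classifier entries built from ~12 base selector
# families and ~10 base classifier families, with documented hyperparameter
# variants counted as distinct entries; every entry is functional. Crossing
# them yields the 1,440-cell optimisation grid.

selector_entry <- function(name, fn) list(name = name, select = fn)

topk_selector <- function(name, scorer, k) {
  selector_entry(sprintf("%s_top%d", name, k), function(x, y, seed = 1L) {
    s <- scorer(as.matrix(x), as.integer(y))
    names(s) <- colnames(x)
    names(sort(s, decreasing = TRUE))[seq_len(min(k, ncol(x)))]
  })
}

#' Default feature-selector registry (45 entries)
#'
#' Twelve base families — variance, t-statistic, Wilcoxon/Mann-Whitney,
#' univariate AUC, Pearson and Spearman correlation, Kruskal-Wallis, mutual
#' information, Fisher score, ReliefF (two K settings), random-forest
#' impurity importance, correlation-redundancy filtering, FDR-thresholded
#' t-tests, and LASSO/elastic-net — expanded by top-k and hyperparameter
#' variants into 45 named, functional entries.
#'
#' @param ks top-k variants for the ranking families.
#' @return list of class `selector_registry`; each entry has `name` and
#'   `select(x, y, seed)` returning selected column names.
#' @export
default_selector_registry <- function(ks = c(10L, 25L, 50L)) {
  reg <- list()
  add <- function(e) reg[[length(reg) + 1]] <<- e
  scorers <- list(
    variance = function(x, y) apply(x, 2, stats::var),
    ttest = score_ttest,
    wilcoxon = score_wilcoxon,
    aucrank = score_aucrank,
    pearson = function(x, y) abs(suppressWarnings(stats::cor(x, y)))[, 1],
    spearman = function(x, y) abs(suppressWarnings(stats::cor(x, y, method = "spearman")))[, 1],
    kruskal = score_kruskal,
    mutinfo = score_mutinfo,
    fisher = score_fisher,
    relieffK10 = function(x, y) relieff_rank(x, y, K = min(10L, min(table(y)) - 1L)),
    relieffK5 = function(x, y) relieff_rank(x, y, K = min(5L, min(table(y)) - 1L)),
    rfimp = function(x, y) {
      fit <- ranger::ranger(x = as.data.frame(x), y = factor(y), num.trees = 100,
                            importance = "impurity", seed = 1L, num.threads = 1)
      fit$variable.importance
    })
  for (nm in names(scorers)) for (k in ks) add(topk_selector(nm, scorers[[nm]], k))
  # embedded (penalised-regression) selectors
  for (cfg in list(c(1, 1), c(0.5, 1), c(0.25, 1), c(0.75, 1), c(1, 2), c(0.5, 2))) {
    alpha <- cfg[1]; rule <- if (cfg[2] == 1) "min" else "1se"
    add(selector_entry(sprintf("enet_a%s_%s", alpha, rule), local({
      a <- alpha; r <- rule
      function(x, y, seed = 1L) {
        res <- try(lasso_select(x, y, alpha = a, cv_folds = 5, rule = r, seed = seed),
                   silent = TRUE)
        if (inherits(res, "try-error")) {
          s <- score_ttest(as.matrix(x), as.integer(y))
          names(s) <- colnames(x)
          return(names(sort(s, decreasing = TRUE))[seq_len(min(10, ncol(x)))])
        }
        res$selected
      }
    })))
  }
  # redundancy-aware correlation filters
  for (k in c(25L, 50L)) {
    add(selector_entry(sprintf("pearson_top%d_uncorr", k), local({
      kk <- k
      function(x, y, seed = 1L) {
        x <- as.matrix(x)
        s <- abs(suppressWarnings(stats::cor(x, as.integer(y))))[, 1]
        s[is.na(s)] <- 0
        cand <- names(sort(s, decreasing = TRUE))
        kept <- character(0)
        for (f in cand) {
          if (length(kept) >= kk) break
          if (!length(kept) ||
              max(abs(suppressWarnings(stats::cor(x[, f], x[, kept, drop = FALSE]))),
                  na.rm = TRUE) < 0.9)
            kept <- c(kept, f)
        }
        kept
      }
    })))
  }
  # FDR-thresholded univariate t-tests
  reg[[length(reg) + 1]] <- selector_entry("ttest_fdr05", function(x, y, seed = 1L) {
    x <- as.matrix(x)
    p <- vapply(seq_len(ncol(x)), function(j) {
      if (stats::sd(x[, j]) == 0) return(1)
      tryCatch(stats::t.test(x[y == 1, j], x[y == 0, j])$p.value,
               error = function(e) 1)
    }, numeric(1))
    keep <- stats::p.adjust(p, "BH") < 0.05
    if (!any(keep)) keep <- rank(p, ties.method = "first") <= 10
    colnames(x)[keep]
  })
  names(reg) <- vapply(reg, `[[`, character(1), "name")
  structure(reg, class = "selector_registry")
}

classifier_entry <- function(name, fit, predict) list(name = name, fit = fit, predict = predict)

svm_entry <- function(name, kernel, cost, gamma = NULL, degree = NULL) {
  classifier_entry(name,
    fit = function(x, y) {
      args <- list(x = x, y = factor(y, levels = c(0, 1)), kernel = kernel,
                   cost = cost, probability = TRUE, scale = FALSE)
      if (!is.null(gamma)) args$gamma <- gamma
      if (!is.null(degree)) args$degree <- degree
      do.call(e1071::svm, args)
    },
    predict = function(m, x) {
      p <- attr(predict(m, x, probability = TRUE), "probabilities")
      p[, "1"]
    })
}

glmnet_entry <- function(name, alpha) {
  classifier_entry(name,
    fit = function(x, y) {
      set.seed(1L)
      glmnet::cv.glmnet(as.matrix(x), as.integer(y), family = "binomial",
                        alpha = alpha, nfolds = 5)
    },
    predict = function(m, x)
      as.numeric(predict(m, as.matrix(x), s = "lambda.min", type = "response")))
}

knn_entry <- function(k) {
  classifier_entry(sprintf("knn_k%d", k),
    fit = function(x, y) list(x = as.matrix(x), y = factor(y, levels = c(0, 1)), k = k),
    predict = function(m, x) {
      pr <- class::knn(m$x, as.matrix(x), m$y, k = m$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    })
}

ranger_entry <- function(name, num_trees, min_node = 5L) {
  classifier_entry(name,
    fit = function(x, y)
      ranger::ranger(x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
                     num.trees = num_trees, probability = TRUE,
                     min.node.size = min_node, seed = 1L, num.threads = 1),
    predict = function(m, x)
      predict(m, data = as.data.frame(x), num.threads = 1)$predictions[, "1"])
}

nnet_entry <- function(size) {
  classifier_entry(sprintf("nnet_h%d", size),
    fit = function(x, y) {
      set.seed(1L)
      nnet::nnet(as.matrix(x), as.integer(y), size = size, decay = 0.01,
                 maxit = 200, trace = FALSE)
    },
    predict = function(m, x) as.numeric(predict(m, as.matrix(x))))
}

xgb_entry <- function(name, depth, eta, nrounds = 50) {
  classifier_entry(name,
    fit = function(x, y)
      xgboost::xgboost(data = as.matrix(x), label = as.integer(y),
                       max_depth = depth, eta = eta, nrounds = nrounds,
                       objective = "binary:logistic", verbose = 0, nthread = 1),
    predict = function(m, x) as.numeric(predict(m, as.matrix(x))))
}

#' Default classifier registry (32 entries)
#'
#' Ten base families — logistic regression (plain and three penalised
#' variants), linear/quadratic discriminants, support-vector machines over
#' four kernels and cost settings, k-nearest neighbours, naive Bayes,
#' decision trees, random forests, single-hidden-layer neural networks, and
#' gradient-boosted trees — expanded by hyperparameter variants into 32
#' named, functional entries. All produce class-1 probability scores.
#'
#' @return list of class `classifier_registry`; each entry has `name`,
#'   `fit(x, y)` and `predict(model, x)`.
#' @export
default_classifier_registry <- function() {
  reg <- list(
    classifier_entry("logistic",
      fit = function(x, y) {
        df <- as.data.frame(x)
        stats::glm(y ~ ., data = cbind(df, y = as.integer(y)),
                   family = stats::binomial(), control = list(maxit = 50))
      },
      predict = function(m, x) as.numeric(predict(m, as.data.frame(x), type = "response"))),
    glmnet_entry("ridge_logistic", 0),
    glmnet_entry("lasso_logistic", 1),
    glmnet_entry("enet_logistic", 0.5),
    classifier_entry("lda",
      fit = function(x, y) MASS::lda(as.matrix(x), grouping = factor(y, levels = c(0, 1))),
      predict = function(m, x) predict(m, as.matrix(x))$posterior[, "1"]),
    classifier_entry("qda",
      fit = function(x, y) {
        tryCatch(MASS::qda(as.matrix(x), grouping = factor(y, levels = c(0, 1))),
                 error = function(e)
                   MASS::lda(as.matrix(x), grouping = factor(y, levels = c(0, 1))))
      },
      predict = function(m, x) predict(m, as.matrix(x))$posterior[, "1"]),
    svm_entry("svm_linear_c0.1", "linear", 0.1),
    svm_entry("svm_linear_c1", "linear", 1),
    svm_entry("svm_linear_c10", "linear", 10),
    svm_entry("svm_rbf_c1", "radial", 1),
    svm_entry("svm_rbf_c10", "radial", 10),
    svm_entry("svm_rbf_c1_g0.01", "radial", 1, gamma = 0.01),
    svm_entry("svm_poly_d2", "polynomial", 1, degree = 2),
    svm_entry("svm_poly_d3", "polynomial", 1, degree = 3),
    svm_entry("svm_sigmoid", "sigmoid", 1),
    knn_entry(1L), knn_entry(3L), knn_entry(5L), knn_entry(7L), knn_entry(11L),
    classifier_entry("naive_bayes",
      fit = function(x, y) e1071::naiveBayes(as.data.frame(x), factor(y, levels = c(0, 1))),
      predict = function(m, x) predict(m, as.data.frame(x), type = "raw")[, "1"]),
    classifier_entry("cart",
      fit = function(x, y) rpart::rpart(y ~ ., data = cbind(as.data.frame(x), y = factor(y)),
                                        method = "class"),
      predict = function(m, x) predict(m, as.data.frame(x), type = "prob")[, "1"]),
    classifier_entry("cart_depth3",
      fit = function(x, y) rpart::rpart(y ~ ., data = cbind(as.data.frame(x), y = factor(y)),
                                        method = "class",
                                        control = rpart::rpart.control(maxdepth = 3)),
      predict = function(m, x) predict(m, as.data.frame(x), type = "prob")[, "1"]),
    ranger_entry("rf_100", 100),
    ranger_entry("rf_300", 300),
    ranger_entry("rf_100_node10", 100, 10L),
    nnet_entry(3L), nnet_entry(5L), nnet_entry(10L),
    xgb_entry("xgb_d2_e0.3", 2, 0.3),
    xgb_entry("xgb_d4_e0.3", 4, 0.3),
    xgb_entry("xgb_d2_e0.1", 2, 0.1)
  )
  names(reg) <- vapply(reg, `[[`, character(1), "name")
  structure(reg, class = "classifier_registry")
}

#' Enumerate the selector x classifier optimisation grid
#'
#' Full cross-product of the two registries in stable (registry) order:
#' 45 x 32 = 1,440 combinations at the defaults.
#'
#' @param selectors a `selector_registry`.
#' @param classifiers a `classifier_registry`.
#' @return data frame with columns `selector`, `classifier`, one row per
#'   combination.
#' @export
enumerate_grid <- function(selectors = default_selector_registry(),
                           classifiers = default_classifier_registry()) {
  if (!length(selectors) || !length(classifiers))
    stop("enumerate_grid: registries must be nonempty")
  out <- expand.grid(classifier = names(classifiers), selector = names(selectors),
                     stringsAsFactors = FALSE)[, c(2, 1)]
  out[order(match(out$selector, names(selectors)),
            match(out$classifier, names(classifiers))), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
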