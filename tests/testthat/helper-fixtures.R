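# Shared fixtures: compact kinetic spec sets and memoized trained models so
# expensive training runs are shared between related tests.

# Five well-separated classes: disjoint amplitude bands and kinetics fast
# enough that every curve reaches its plateau inside a 30-min window
# (onset + 3.5 * rise stays well under 30 min), so the bands translate
# into separated endpoint distributions at every cut length.
separated_specs <- function() {
  list(
    A = class_kinetic_spec("A", c(100, 250), onset_delay = c(4, 1),
                           rise_time = c(3, 0.5)),
    B = class_kinetic_spec("B", c(400, 550), onset_delay = c(6, 1),
                           rise_time = c(3, 0.5)),
    C = class_kinetic_spec("C", c(700, 850), onset_delay = c(8, 1.5),
                           rise_time = c(4, 0.5)),
    D = class_kinetic_spec("D", c(1000, 1150), onset_delay = c(5, 1),
                           rise_time = c(3, 0.5)),
    E = class_kinetic_spec("E", c(1300, 1500), onset_delay = c(7, 1),
                           rise_time = c(4, 0.5))
  )
}

# Two classes identical in distribution until minute 60; class "late" gains
# a second adhesion phase (onset ~75 min). Discriminative information lives
# entirely in the final third of a 90-min window.
late_difference_specs <- function() {
  base <- list(amplitude_range = c(250, 350), onset_delay = c(5, 1),
               rise_time = c(6, 1))
  list(
    early = class_kinetic_spec("early", base$amplitude_range,
                               onset_delay = base$onset_delay,
                               rise_time = base$rise_time),
    late = class_kinetic_spec("late", base$amplitude_range,
                              onset_delay = base$onset_delay,
                              rise_time = base$rise_time,
                              second_phase = list(
                                amplitude_range = c(300, 450),
                                onset_delay = c(75, 3),
                                rise_time = c(4, 1)))
  )
}

# Fast kinetics + zero plateau slope: curves reach their amplitude exactly
# (to machine precision) well before the end of a 150-min recording.
conservation_spec <- function() {
  list(A = class_kinetic_spec("A", c(150, 600), onset_delay = c(5, 1),
                              rise_time = c(3, 0.5)))
}

# Memoized heavy artifacts, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, build(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# FCN trained on the late-difference task at the 90-min cut, at a coarse
# 54-s frame period (all lengths stay delta-t parameterized); shared by
# the accuracy-vs-length and grad-CAM localization tests. FCN's
# global-average-pooling head makes it the canonical grad-CAM subject.
late_task_fit <- function() {
  memo("late_task_fit", function() {
    dt <- 54
    tg <- time_grid(90, dt)
    rec <- generate_labeled_dataset(c(early = 150L, late = 150L),
                                    late_difference_specs(), tg,
                                    noise_sd = 10, seed = 402L)
    ds <- cut_to_length(rec, 90, dt)
    folds <- stratified_kfold_split(ds$y, 5, seed = 403L)
    tr <- folds$folds[[1]]$train
    te <- folds$folds[[1]]$test
    std <- standardize_signals(ds$X[tr, ], ds$X[te, ])
    cfg <- train_config("FCN", epochs = 25,
                        early_stopping_patience = 8, seed = 404L)
    model <- build_model("FCN", ncol(ds$X), 2, seed = 405L)
    model <- train_model(model, list(X = std$train, y = ds$y[tr]),
                         list(X = std$others[[1]], y = ds$y[te]), cfg)
    list(model = model, test_X = std$others[[1]], test_y = ds$y[te],
         records = rec, dataset = ds, delta_t_s = dt,
         train = tr, test = te)
  })
}
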