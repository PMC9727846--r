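Package: imputeclass
Title: Simulation Framework for Binary Classification on Imputed Missing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulation studies of how imputed numerical missing data
    affect binary classification, motivated by breast-cancer recurrence
    prediction. Generates multivariate-normal datasets with a dichotomized
    outcome, amputes them under MCAR and MAR mechanisms at controlled
    missingness rates, imputes with six algorithms (series mean, hot deck,
    k-nearest neighbour, multiple imputation by chained equations, predictive
    mean matching, and bootstrap expectation-maximisation), classifies with
    binary logistic regression and linear/quadratic discriminant analysis, and
    evaluates imputation RMSE, classification accuracy, and area under the ROC
    curve over a full factorial grid with replication.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
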