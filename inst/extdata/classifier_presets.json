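{
  "_comment": "Classifier configurations per experiment. MLP: learning rate L, momentum M, hidden sigmoid units H, training epochs N, weight-init seed S (inputs rescaled to [-1,1] from train ranges, as in the Weka default). SVM: RBF kernel, cost C, gamma G (inputs rescaled to [0,1] from train ranges, standard LibSVM practice). KNN: k neighbors, distance in {euclidean, manhattan}. MNLR: ridge penalty R, fitted by BFGS.",
  "exp1_face": {
    "mlp":  {"family": "mlp",  "L": 0.2045, "M": 0.1909, "H": 59, "N": 5000, "S": 0},
    "svm":  {"family": "svm",  "C": 1000, "G": 0.1, "kernel": "rbf"},
    "knn":  {"family": "knn",  "k": 1, "distance": "euclidean"},
    "mnlr": {"family": "mnlr", "R": 1e-8}
  },
  "exp1_eyes": {
    "mlp":  {"family": "mlp",  "L": 0.2045, "M": 0.1909, "H": 59, "N": 5000, "S": 0},
    "svm":  {"family": "svm",  "C": 1000, "G": 0.001, "kernel": "rbf"},
    "knn":  {"family": "knn",  "k": 1, "distance": "euclidean"},
    "mnlr": {"family": "mnlr", "R": 1e-8}
  },
  "exp1_mouth": {
    "mlp":  {"family": "mlp",  "L": 0.2045, "M": 0.1909, "H": 59, "N": 5000, "S": 0},
    "svm":  {"family": "svm",  "C": 1000, "G": 0.01, "kernel": "rbf"},
    "knn":  {"family": "knn",  "k": 1, "distance": "euclidean"},
    "mnlr": {"family": "mnlr", "R": 1e-8}
  },
  "exp2_test1_eyes": {
    "mlp":  {"family": "mlp",  "L": 0.2045, "M": 0.1909, "H": 59, "N": 500, "S": 2},
    "svm":  {"family": "svm",  "C": 1000, "G": 1.0, "kernel": "rbf"},
    "knn":  {"family": "knn",  "k": 1, "distance": "manhattan"},
    "mnlr": {"family": "mnlr", "R": 1e-8}
  },
  "exp2_test1_mouth": {
    "mlp":  {"family": "mlp",  "L": 0.2045, "M": 0.1909, "H": 59, "N": 2000, "S": 37},
    "svm":  {"family": "svm",  "C": 1000, "G": 1.0, "kernel": "rbf"},
    "knn":  {"family": "knn",  "k": 1, "distance": "manhattan"},
    "mnlr": {"family": "mnlr", "R": 1e-8}
  },
  "exp2_test2_eyes": {
    "mlp":  {"family": "mlp",  "L": 0.2045, "M": 0.1909, "H": 59, "N": 1000, "S": 87},
    "svm":  {"family": "svm",  "C": 10, "G": 1.0, "kernel": "rbf"},
    "knn":  {"family": "knn",  "k": 1, "distance": "manhattan"},
    "mnlr": {"family": "mnlr", "R": 1e-8}
  },
  "exp2_test2_mouth": {
    "mlp":  {"family": "mlp",  "L": 0.2045, "M": 0.1909, "H": 59, "N": 500, "S": 7},
    "svm":  {"family": "svm",  "C": 10, "G": 1.0, "kernel": "rbf"},
    "knn":  {"family": "knn",  "k": 1, "distance": "manhattan"},
    "mnlr": {"family": "mnlr", "R": 1e-8}
  },
  "exp3_test1_eyes": {
    "mlp":  {"family": "mlp",  "L": 0.2045, "M": 0.1909, "H": 59, "N": 1000, "S": 18},
    "svm":  {"family": "svm",  "C": 10, "G": 1.0, "kernel": "rbf"},
    "knn":  {"family": "knn",  "k": 1, "distance": "manhattan"},
    "mnlr": {"family": "mnlr", "R": 1e-8}
  },
  "exp3_test1_mouth": {
    "mlp":  {"family": "mlp",  "L": 0.2045, "M": 0.1909, "H": 59, "N": 7000, "S": 25},
    "svm":  {"family": "svm",  "C": 1000, "G": 1.0, "kernel": "rbf"},
    "knn":  {"family": "knn",  "k": 1, "distance": "manhattan"},
    "mnlr": {"family": "mnlr", "R": 1e-8}
  },
  "exp3_test2_eyes": {
    "mlp":  {"family": "mlp",  "L": 0.2045, "M": 0.1909, "H": 59, "N": 4000, "S": 18},
    "svm":  {"family": "svm",  "C": 10, "G": 1.0, "kernel": "rbf"},
    "knn":  {"family": "knn",  "k": 1, "distance": "manhattan"},
    "mnlr": {"family": "mnlr", "R": 1e-8}
  },
  "exp3_test2_mouth": {
    "mlp":  {"family": "mlp",  "L": 0.2045, "M": 0.1909, "H": 59, "N": 7000, "S": 25},
    "svm":  {"family": "svm",  "C": 10, "G": 1.0, "kernel": "rbf"},
    "knn":  {"family": "knn",  "k": 1, "distance": "euclidean"},
    "mnlr": {"family": "mnlr", "R": 1e-8}
  }
}
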