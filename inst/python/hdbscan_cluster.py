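"""HDBSCAN helper: csv_in csv_out min_cluster_size min_samples epsilon selection."""
import sys
import warnings

import numpy as np

warnings.filterwarnings("ignore")


def main(argv):
    csv_in, csv_out, mcs, ms, eps, selection = argv
    X = np.loadtxt(csv_in, delimiter=",", ndmin=2)
    from sklearn.cluster import HDBSCAN

    labels = HDBSCAN(
        min_cluster_size=int(mcs),
        min_samples=int(ms),
        cluster_selection_epsilon=float(eps),
        cluster_selection_method=selection,
        copy=True,
    ).fit_predict(X)
    np.savetxt(csv_out, labels, fmt="%d")


if __name__ == "__main__":
    main(sys.argv[1:7])
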