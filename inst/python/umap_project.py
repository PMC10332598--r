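"""UMAP projection helper: csv_in csv_out n_dims seed n_neighbors min_dist."""
import sys
import warnings

import numpy as np

warnings.filterwarnings("ignore")


def main(argv):
    csv_in, csv_out, n_dims, seed, n_neighbors, min_dist = argv
    X = np.loadtxt(csv_in, delimiter=",", ndmin=2)
    import umap  # deferred: slow import

    emb = umap.UMAP(
        n_components=int(n_dims),
        random_state=int(seed),
        n_neighbors=int(n_neighbors),
        min_dist=float(min_dist),
    ).fit_transform(X)
    np.savetxt(csv_out, emb, delimiter=",")


if __name__ == "__main__":
    main(sys.argv[1:7])
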