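"""Convert AnnData .h5ad files to/from the plain-text exchange layout.

Exchange layout (10x-style directory):
  matrix.mtx    genes x obs MatrixMarket
  genes.tsv     one gene ID per line
  barcodes.tsv  one obs ID per line
  spliced.mtx / unspliced.mtx   optional layers, genes x obs
  coords.csv    optional: obs_id,x,y
  obs_meta.csv  optional: obs_id[,label][,pseudotime]

Usage:
  python h5ad_bridge.py to-exchange   input.h5ad  out_dir
  python h5ad_bridge.py from-exchange in_dir      output.h5ad
"""
import os
import sys

import numpy as np
import scipy.sparse as sp
import scipy.io as sio
import anndata as ad


def _write_mtx(path, mat):
    m = sp.csc_matrix(mat)
    sio.mmwrite(path, m.T, precision=17)  # genes x obs


def to_exchange(h5ad_path, out_dir):
    adata = ad.read_h5ad(h5ad_path)
    os.makedirs(out_dir, exist_ok=True)
    _write_mtx(os.path.join(out_dir, "matrix.mtx"), adata.X)
    with open(os.path.join(out_dir, "genes.tsv"), "w") as fh:
        fh.write("\n".join(map(str, adata.var_names)) + "\n")
    with open(os.path.join(out_dir, "barcodes.tsv"), "w") as fh:
        fh.write("\n".join(map(str, adata.obs_names)) + "\n")
    for layer in ("spliced", "unspliced"):
        if layer in adata.layers:
            _write_mtx(os.path.join(out_dir, layer + ".mtx"), adata.layers[layer])
    if "spatial" in adata.obsm:
        xy = np.asarray(adata.obsm["spatial"], dtype=float)
        with open(os.path.join(out_dir, "coords.csv"), "w") as fh:
            fh.write("obs_id,x,y\n")
            for name, (x, y) in zip(adata.obs_names, xy[:, :2]):
                fh.write(f"{name},{float(x)!r},{float(y)!r}\n")
    cols = [c for c in ("cell_type", "pseudotime") if c in adata.obs.columns]
    if cols:
        with open(os.path.join(out_dir, "obs_meta.csv"), "w") as fh:
            header = ["obs_id"] + ["label" if c == "cell_type" else c for c in cols]
            fh.write(",".join(header) + "\n")
            for i, name in enumerate(adata.obs_names):
                vals = [str(name)]
                for c in cols:
                    v = adata.obs[c].iloc[i]
                    vals.append(repr(float(v)) if c == "pseudotime" else str(v))
                fh.write(",".join(vals) + "\n")


def from_exchange(in_dir, h5ad_path):
    X = sio.mmread(os.path.join(in_dir, "matrix.mtx")).T.tocsr()
    genes = open(os.path.join(in_dir, "genes.tsv")).read().splitlines()
    obs = open(os.path.join(in_dir, "barcodes.tsv")).read().splitlines()
    adata = ad.AnnData(X=X)
    adata.var_names = genes
    adata.obs_names = obs
    for layer in ("spliced", "unspliced"):
        f = os.path.join(in_dir, layer + ".mtx")
        if os.path.exists(f):
            adata.layers[layer] = sio.mmread(f).T.tocsr()
    cf = os.path.join(in_dir, "coords.csv")
    if os.path.exists(cf):
        rows = open(cf).read().splitlines()[1:]
        order = {name: i for i, name in enumerate(obs)}
        xy = np.zeros((len(obs), 2))
        for row in rows:
            name, x, y = row.split(",")
            xy[order[name]] = (float(x), float(y))
        adata.obsm["spatial"] = xy
    mf = os.path.join(in_dir, "obs_meta.csv")
    if os.path.exists(mf):
        lines = open(mf).read().splitlines()
        header = lines[0].split(",")
        order = {name: i for i, name in enumerate(obs)}
        cols = {h: [None] * len(obs) for h in header[1:]}
        for row in lines[1:]:
            parts = row.split(",")
            for h, v in zip(header[1:], parts[1:]):
                cols[h][order[parts[0]]] = v
        if "label" in cols:
            adata.obs["cell_type"] = cols["label"]
        if "pseudotime" in cols:
            adata.obs["pseudotime"] = np.array(cols["pseudotime"], dtype=float)
    adata.write_h5ad(h5ad_path)


def main(argv):
    if len(argv) != 3 or argv[0] not in ("to-exchange", "from-exchange"):
        sys.stderr.write(__doc__)
        return 2
    if argv[0] == "to-exchange":
        to_exchange(argv[1], argv[2])
    else:
        from_exchange(argv[1], argv[2])
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv[1:]))
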