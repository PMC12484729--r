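"""Build or read a five-sheet results workbook from/to CSV mirrors.

Usage:
  python workbook.py write <out.xlsx> <sheet1_name> <sheet1.csv> [...]
  python workbook.py read <in.xlsx> <out_dir>

The write mode creates one worksheet per (name, csv) pair, in order, typing
cells as numbers when the CSV field parses as one. The read mode dumps every
worksheet back to <out_dir>/<index>_<name>.csv.
"""
import csv
import re
import sys

import openpyxl


def _maybe_number(s):
    if s == "":
        return None
    try:
        f = float(s)
    except ValueError:
        return s
    if re.fullmatch(r"[+-]?\d+", s):
        i = int(s)
        if abs(i) < 2**53:
            return i
    return f


def write(out_path, pairs):
    wb = openpyxl.Workbook()
    wb.remove(wb.active)
    for name, csv_path in pairs:
        ws = wb.create_sheet(title=name[:31])
        with open(csv_path, newline="") as fh:
            for r, row in enumerate(csv.reader(fh), start=1):
                for c, val in enumerate(row, start=1):
                    ws.cell(row=r, column=c,
                            value=val if r == 1 else _maybe_number(val))
    wb.save(out_path)


def read(in_path, out_dir):
    wb = openpyxl.load_workbook(in_path, read_only=True)
    for i, name in enumerate(wb.sheetnames, start=1):
        ws = wb[name]
        safe = re.sub(r"[^A-Za-z0-9_-]+", "_", name)
        with open(f"{out_dir}/{i:02d}_{safe}.csv", "w", newline="") as fh:
            w = csv.writer(fh)
            for row in ws.iter_rows(values_only=True):
                w.writerow(["" if v is None else v for v in row])
    print("\n".join(wb.sheetnames))


if __name__ == "__main__":
    mode = sys.argv[1]
    if mode == "write":
        args = sys.argv[3:]
        write(sys.argv[2], list(zip(args[::2], args[1::2])))
    elif mode == "read":
        read(sys.argv[2], sys.argv[3])
    else:
        raise SystemExit(f"unknown mode: {mode}")
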