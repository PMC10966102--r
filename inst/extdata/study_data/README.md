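# Study data drop-in

The deposited supplementary tables of the 250-beer study (Zenodo accession
10653704) are not redistributed with this package. To run the printed-value
acceptance checks against them, place here:

- `chemistry.csv` — beers x chemical properties, with leading columns
  `beer_id`, `style`, `abv` (and optionally `price_per_l`), one numeric
  column per measured property (Supplementary Data 4 layout).
- `panel.csv` — long-format trained-panel scores with columns `beer_id`,
  `taster_id`, `session_id`, `attribute`, `score` (Supplementary Data 7
  layout).

Without these files the corresponding acceptance tests report the missing
data explicitly; everything else in the package runs on synthetic bundles.
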