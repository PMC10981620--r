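# Editable immunological vocabulary for the GO keyword filter.
# `keywords` drives term retention; `categories` drives the 7-theme
# breakdown of retained terms. All matching is case-insensitive substring.
keywords:
  - immune
  - immun
  - inflamm
  - leukocyte
  - lymphocyte
  - t cell
  - b cell
  - cytokine
  - chemokine
  - interferon
  - interleukin
  - antigen
  - mhc
  - natural killer
  - macrophage
  - dendritic
  - phagocyt
  - complement
  - toll-like
  - myeloid
categories:
  immune response regulation:
    - regulation of immune
    - immune response
    - immune system
  inflammatory response:
    - inflamm
  lymphocyte activation & differentiation:
    - lymphocyte
    - t cell
    - b cell
    - natural killer
  myeloid/dendritic cell activation:
    - myeloid
    - dendritic
    - macrophage
    - phagocyt
  antigen processing & presentation:
    - antigen
    - mhc
  cytokine production & signalling:
    - cytokine
    - chemokine
    - interferon
    - interleukin
  leukocyte migration:
    - leukocyte migration
    - chemotaxis
    - leukocyte
match_fields:
  - name
  - description
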