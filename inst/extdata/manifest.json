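{
  "fixtures": [
    {
      "name": "table1",
      "provenance": "paper_table",
      "files": [
        {
          "name": "table1.tsv",
          "md5": "5d28611a7a6b60b1a444d837bd1de8b7"
        }
      ]
    },
    {
      "name": "synthetic_study",
      "provenance": "synthetic",
      "files": [
        {
          "name": "synthetic_study/genome.fa",
          "md5": "960957b6b52f945133df47a857a30bf0"
        },
        {
          "name": "synthetic_study/tss.tsv",
          "md5": "9664181ecd840f465e4413554ab40619"
        },
        {
          "name": "synthetic_study/peaks.bed",
          "md5": "4323ca536d2489441e1da6fd6d1e29f9"
        },
        {
          "name": "synthetic_study/calls_frag1.ibed",
          "md5": "da78204cd393d5f867c9387cc54e1382"
        },
        {
          "name": "synthetic_study/calls_frag4.ibed",
          "md5": "47adefc212a06b8ef88221e37b555e50"
        },
        {
          "name": "synthetic_study/proxies.csv",
          "md5": "583e9229243b005e9ed627bc89375085"
        },
        {
          "name": "synthetic_study/expression.tsv",
          "md5": "8cb39e74fc0e87d397c405be677a1ff3"
        },
        {
          "name": "synthetic_study/truth.json",
          "md5": "644157b3b14465020701d7c16b3a7f5f"
        }
      ]
    }
  ]
}
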