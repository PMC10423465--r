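# Drug metadata and market parameters for the Poland 2013-2021 TNF-inhibitor
# reimbursement fixture. DDDs are WHO defined daily doses in milligrams;
# population is the national average over the analysed period; pln_per_eur is
# the 5-year average exchange rate used to express payer spending in euro.
population: 38000000
pln_per_eur: 4.4124
drugs:
  INF:
    name: infliximab
    first_biosimilar_year: 2014
    ddd_mg: 3.75
    products:
      - {name: Remicade,  biosimilar: false, from: 2013, to: 2021}
      - {name: Remsima,   biosimilar: true,  from: 2014, to: 2021}
      - {name: Inflectra, biosimilar: true,  from: 2014, to: 2021}
      - {name: Flixabi,   biosimilar: true,  from: 2018, to: 2021}
      - {name: Zessly,    biosimilar: true,  from: 2019, to: 2021}
  ETN:
    name: etanercept
    first_biosimilar_year: 2016
    ddd_mg: 7
    products:
      - {name: Enbrel,   biosimilar: false, from: 2013, to: 2021}
      - {name: Benepali, biosimilar: true,  from: 2016, to: 2021}
      - {name: Erelzi,   biosimilar: true,  from: 2017, to: 2021}
  ADA:
    name: adalimumab
    first_biosimilar_year: 2019
    ddd_mg: 2.9
    products:
      - {name: Humira,   biosimilar: false, from: 2013, to: 2021}
      - {name: Imraldi,  biosimilar: true,  from: 2019, to: 2021}
      - {name: Amgevita, biosimilar: true,  from: 2019, to: 2021}
      - {name: Hyrimoz,  biosimilar: true,  from: 2019, to: 2021}
      - {name: Idacio,   biosimilar: true,  from: 2020, to: 2021}
# Reference years used in the published analysis: the estimated model anchors
# each drug at the year preceding first biosimilar reimbursement; the
# real-life model anchors infliximab at its 2018 expenditure peak.
reference_years:
  estimated:  {INF: 2013, ETN: 2015, ADA: 2018}
  real_life:  {INF: 2018, ETN: 2015, ADA: 2018}
  real_life_alternative: {INF: 2013, ETN: 2015, ADA: 2018}
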