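{"volumes":{"lv":92.955112,"la":113.627833,"rv":81.005839,"ra":64.102368,"aop":91.848538,"haa":12.003128,"lna":7.409503,"lca":7.409503,"rica":9.009729,"rula":9.009729,"lica":8.994532,"lula":8.994532,"sap":226.641249,"sv":2553.132838,"vc":154.637084,"rsv":175.837883,"rijv":175.837883,"lijv":174.992257,"lsv":174.992257,"lpap":32.562804,"rpap":32.562804,"lpad":81.148968,"rpad":81.148968,"lpv":170.56733,"rpv":170.56733},"flows":{"aop_haa":-2.23222,"aop_lna":-1.275774,"aop_lca":-1.275774,"aop_sap":56.96587,"Dp_l":0,"Dp_r":0}}
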