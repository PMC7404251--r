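>AprBp synthetic subtilisin-like protease construct (381 aa)
VLKLGALSLLAGSTLVAAPSALAQSVSHAGASTLVKGASTLVKGASTLVKGASTLVKGAS
TLVKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKAGASTLVKGASTLV
KGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKGAS
TLVKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKAGCSTLV
KNAVDTANNRGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKA
PAVHAQGYKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKGA
STLVKLENTATPLGNSFYYGK
>GseBp synthetic glutamyl endopeptidase construct (303 aa)
VLSGALLLAGSTLVAAPSALAQSVHAGASTLVKGASTLVKGASTLVKGASTLVKGASTLV
KGASTLVKGASTLVKGASTLVKAGSTLVGASTLVKGASTLVKGASTLVKGASTLVKGAST
LVKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKG
ASTLVKAGRTDTNIGNTVGYRGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKGAST
LVKISGYPGDKGASTLVKGASTLVKGASTLVKGASTLVKGASTLVKGGDRATAAFVEFIN
YAK
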