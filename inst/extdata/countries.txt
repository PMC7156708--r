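afghanistan
argentina
australia
austria
bangladesh
belgium
brazil
canada
chile
china
colombia
cuba
denmark
ecuador
egypt
england
ethiopia
finland
france
germany
ghana
greece
guatemala
haiti
honduras
india
indonesia
iran
iraq
ireland
israel
italy
jamaica
japan
jordan
kenya
korea
laos
lebanon
mexico
morocco
nepal
netherlands
nicaragua
nigeria
norway
pakistan
peru
philippines
poland
portugal
russia
samoa
scotland
somalia
spain
sweden
switzerland
syria
taiwan
thailand
turkey
uganda
ukraine
vietnam
yemen
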